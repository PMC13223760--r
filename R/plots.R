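#' Density of stop-codon distances by class and novelty
#'
#' Distribution of each transcript's maximal 3UI distance to the stop codon
#' (the flagged records), split by annotated/novel status, with the NMD-rule
#' threshold marked.
#'
#' @param records Record tibble from [classify_utr_introns()].
#' @param threshold NMD-rule threshold to mark (default 55 nt).
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(records, threshold = 55) {
  df <- records[records$max_distance_flag, , drop = FALSE]
  df$novelty <- ifelse(df$novel, "novel", "annotated")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_to_stop,
                                   colour = .data$novelty)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = "distance from stop codon to 3UI donor (nt, spliced)",
                  y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Intron length by class
#'
#' @param records Record tibble with a `length_nt` column (see
#'   [add_intron_features()]); computed from coordinates when absent.
#' @return A ggplot object.
#' @export
plot_intron_lengths <- function(records) {
  df <- records
  if (!"length_nt" %in% names(df)) {
    df$length_nt <- df$intron_end - df$intron_start
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$klass, y = .data$length_nt)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "intron length (nt)") +
    ggplot2::theme_minimal()
}

#' Per-sample mean PSO by condition
#'
#' @param pso_summary Output of [sample_average_pso()] including a
#'   `condition` column.
#' @return A ggplot object.
#' @export
plot_sample_pso <- function(pso_summary) {
  ggplot2::ggplot(pso_summary,
                  ggplot2::aes(x = .data$condition, y = .data$mean_pso)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$klass)) +
    ggplot2::labs(x = NULL, y = "mean PSO per sample") +
    ggplot2::theme_minimal()
}
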