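#' Percent spliced out from percent spliced in
#'
#' PSO = 1 - PSI, where PSI is the inclusion (retention) level of a retained
#' intron event. Missing values are preserved.
#'
#' @param psi Wide tibble: an `event_id` column plus one numeric column per
#'   sample, values in `[0, 1]` or `NA`.
#' @return Tibble of the same shape with values replaced by `1 - value`.
#' @export
pso_from_psi <- function(psi) {
  stopifnot("event_id" %in% names(psi))
  sample_cols <- setdiff(names(psi), "event_id")
  vals <- as.matrix(psi[, sample_cols, drop = FALSE])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    abort("PSI values must lie in [0, 1]",
          class = "utrintrons_validation_error")
  }
  psi[, sample_cols] <- 1 - vals
  psi
}

#' Naive PSI estimate from junction counts
#'
#' Inclusion / (inclusion + skipping) per sample. This is a plain count ratio
#' for quick synthetic work, not the model-based estimate produced by
#' event-level splicing tools.
#'
#' @param inclusion,skipping Matrices or data frames of non-negative counts
#'   with identical dimensions (events x samples).
#' @return Matrix of PSI values; `NA` where both counts are zero.
#' @export
naive_psi <- function(inclusion, skipping) {
  inc <- as.matrix(inclusion)
  skp <- as.matrix(skipping)
  stopifnot(all(dim(inc) == dim(skp)))
  tot <- inc + skp
  out <- inc / tot
  out[tot == 0] <- NA_real_
  out
}

#' Per-sample class-averaged PSO
#'
#' Unweighted mean PSO over the non-missing events of each class, per sample.
#'
#' @param pso Wide PSO tibble (`event_id` plus sample columns).
#' @param event_classes Tibble `event_id`, `klass` labelling each event
#'   (`e3UI` or `co3UI`).
#' @param sample_sheet Optional tibble `sample`, `condition` appended to the
#'   output.
#' @return Tibble `sample`, `klass`, `mean_pso`, `n_events` (and `condition`
#'   when a sample sheet is given). `mean_pso` is `NA` with a warning when a
#'   sample has no usable event of a class.
#' @export
sample_average_pso <- function(pso, event_classes, sample_sheet = NULL) {
  long <- tidyr::pivot_longer(pso, -"event_id", names_to = "sample",
                              values_to = "pso")
  long <- inner_join(long, event_classes[, c("event_id", "klass")],
                     by = "event_id")
  out <- long |>
    group_by(.data$sample, .data$klass) |>
    summarise(mean_pso = if (all(is.na(.data$pso))) NA_real_ else
                mean(.data$pso, na.rm = TRUE),
              n_events = sum(!is.na(.data$pso)), .groups = "drop")
  if (any(is.na(out$mean_pso))) {
    warn("some sample/class combinations have no usable events; mean PSO is NA")
  }
  if (!is.null(sample_sheet)) {
    out <- left_join(out, sample_sheet[, c("sample", "condition")],
                     by = "sample")
  }
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of a sample's count to the gene's geometric mean, using only
#' genes with a positive geometric mean (the standard count normalization of
#' differential-expression analysis).
#'
#' @param counts Gene x sample matrix of non-negative counts, or a tibble
#'   with a `gene_id` column.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  m <- counts_matrix(counts)
  if (!any(apply(m, 1, function(r) all(r > 0)))) {
    abort("no gene has a positive count in every sample; size factors are undefined",
          class = "utrintrons_validation_error")
  }
  DESeq2::estimateSizeFactorsForMatrix(m)
}

#' Divide counts by size factors
#'
#' @param counts As in [size_factors_median_ratio()].
#' @param factors Named size factors; computed when omitted.
#' @return Normalized matrix (genes x samples).
#' @export
normalize_counts <- function(counts, factors = size_factors_median_ratio(counts)) {
  m <- counts_matrix(counts)
  sweep(m, 2, factors[colnames(m)], "/")
}

counts_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot("gene_id" %in% names(counts))
    m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
    rownames(m) <- counts$gene_id
    m
  } else {
    as.matrix(counts)
  }
}

#' Spearman correlation with tie-aware t approximation
#'
#' Rank correlation over pairwise-complete observations; the two-sided
#' p-value uses the t approximation. Fewer than 4 complete pairs, or a
#' zero-variance vector, give a missing result.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `rho`, `p` and `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 4) return(list(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; missing values are passed through.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]",
          class = "utrintrons_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Fisher-z comparison of two independent correlations
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a two-sided
#' normal p-value.
#'
#' @param r1,r2 Correlation coefficients with `|r| < 1`.
#' @param n1,n2 Group sizes, each greater than 3.
#' @return A list with `z` and `p`.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (any(c(n1, n2) <= 3)) {
    abort("both groups need more than 3 observations",
          class = "utrintrons_validation_error")
  }
  if (any(abs(c(r1, r2)) >= 1)) {
    abort("correlations must satisfy |r| < 1",
          class = "utrintrons_validation_error")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}
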