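#' Per-gene correlation of expression with class-averaged PSO
#'
#' Within each condition, the Spearman correlation between a gene's
#' normalized expression across samples and the per-sample mean PSO of a 3UI
#' class; p-values are Benjamini-Hochberg adjusted over genes within each
#' (condition, class) stratum (or globally), and each gene's normal/cancer
#' correlations are compared with the Fisher-z test for independent groups.
#'
#' @param expr Normalized gene expression: matrix (genes x samples) or tibble
#'   with a `gene_id` column.
#' @param pso_summary Output of [sample_average_pso()] (must include
#'   `condition`, either via its `sample_sheet` argument or joined here).
#' @param sample_sheet Optional tibble `sample`, `condition`; required when
#'   `pso_summary` lacks a `condition` column.
#' @param conditions Length-2 character vector naming the reference and
#'   comparison conditions (default `c("normal", "cancer")`).
#' @param bh_family `"stratum"` (default): adjust within each
#'   (condition, class); `"global"`: one family across everything.
#' @return A tibble of class `utr_cor`: one row per (gene, class) with
#'   `rho_normal`, `p_normal`, `padj_normal`, `n_normal`, the `_cancer`
#'   counterparts, and `z_diff`, `p_diff`. Conditions with fewer than 4
#'   samples yield missing columns with a warning.
#' @export
correlate_genes <- function(expr, pso_summary, sample_sheet = NULL,
                            conditions = c("normal", "cancer"),
                            bh_family = c("stratum", "global")) {
  bh_family <- match.arg(bh_family)
  m <- counts_matrix(expr)
  if (!"condition" %in% names(pso_summary)) {
    if (is.null(sample_sheet)) {
      abort("pso_summary lacks a condition column and no sample_sheet given",
            class = "utrintrons_validation_error")
    }
    pso_summary <- left_join(pso_summary,
                             sample_sheet[, c("sample", "condition")],
                             by = "sample")
  }
  stopifnot(length(conditions) == 2)
  genes <- rownames(m)
  classes <- sort(unique(pso_summary$klass))

  one_stratum <- function(cond, kl) {
    sub <- pso_summary[pso_summary$condition == cond &
                         pso_summary$klass == kl, ]
    sub <- sub[sub$sample %in% colnames(m) & !is.na(sub$mean_pso), ]
    if (nrow(sub) < 4) {
      warn(paste0("condition ", cond, " has fewer than 4 usable samples for ",
                  kl, "; correlations set to NA"))
      return(tibble(gene_id = genes, klass = kl, rho = NA_real_, p = NA_real_,
                    n = nrow(sub)))
    }
    pso_vec <- setNames(sub$mean_pso, sub$sample)
    res <- lapply(genes, function(g) {
      spearman_cor(m[g, names(pso_vec)], pso_vec)
    })
    tibble(gene_id = genes, klass = kl,
           rho = map_dbl(res, "rho"), p = map_dbl(res, "p"),
           n = map_int(res, function(r) as.integer(r$n)))
  }

  strata <- list()
  for (kl in classes) {
    for (cond in conditions) {
      s <- one_stratum(cond, kl)
      s$condition <- cond
      s$padj <- if (bh_family == "stratum") bh_adjust(s$p) else NA_real_
      strata[[paste(kl, cond)]] <- s
    }
  }
  all_strata <- bind_rows(strata)
  if (bh_family == "global") {
    all_strata$padj <- bh_adjust(all_strata$p)
  }

  wide <- tidyr::pivot_wider(
    all_strata, id_cols = c("gene_id", "klass"), names_from = "condition",
    values_from = c("rho", "p", "padj", "n"), names_sep = "_")
  ca <- conditions[1]
  cb <- conditions[2]
  zp <- pmap(list(wide[[paste0("rho_", ca)]], wide[[paste0("n_", ca)]],
                  wide[[paste0("rho_", cb)]], wide[[paste0("n_", cb)]]),
             function(r1, n1, r2, n2) {
               if (is.na(r1) || is.na(r2) || n1 <= 3 || n2 <= 3 ||
                   abs(r1) >= 1 || abs(r2) >= 1) {
                 return(list(z = NA_real_, p = NA_real_))
               }
               fisher_z_diff(r1, n1, r2, n2)
             })
  wide$z_diff <- map_dbl(zp, "z")
  wide$p_diff <- map_dbl(zp, "p")
  class(wide) <- c("utr_cor", class(wide))
  attr(wide, "conditions") <- conditions
  attr(wide, "bh_family") <- bh_family
  wide
}

#' Tidy a correlation screen
#'
#' One row per (gene, class, condition) with `rho`, `p`, `padj`, `n` columns.
#'
#' @param x A `utr_cor` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.utr_cor <- function(x, ...) {
  conditions <- attr(x, "conditions")
  out <- as_tibble(unclass_utr_cor(x))
  tidyr::pivot_longer(
    out,
    cols = tidyr::matches(paste0("^(rho|p|padj|n)_(",
                                 paste(conditions, collapse = "|"), ")$")),
    names_to = c(".value", "condition"),
    names_pattern = "^(rho|p|padj|n)_(.*)$")
}

#' Summarise a correlation screen
#'
#' @param x A `utr_cor` object.
#' @param alpha Adjusted-p threshold for the significance counts.
#' @param ... Unused.
#' @return One-row tibble with gene counts and significance tallies.
#' @export
glance.utr_cor <- function(x, alpha = 0.05, ...) {
  conditions <- attr(x, "conditions")
  tibble(
    n_genes = length(unique(x$gene_id)),
    n_classes = length(unique(x$klass)),
    n_sig_a = sum(x[[paste0("padj_", conditions[1])]] < alpha, na.rm = TRUE),
    n_sig_b = sum(x[[paste0("padj_", conditions[2])]] < alpha, na.rm = TRUE),
    n_sig_diff = sum(x$p_diff < alpha, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

unclass_utr_cor <- function(x) {
  class(x) <- setdiff(class(x), "utr_cor")
  x
}

#' Plot a correlation screen
#'
#' Scatter of the two conditions' correlation coefficients per gene, faceted
#' by 3UI class, with genes whose between-condition difference is significant
#' highlighted.
#'
#' @param object A `utr_cor` object.
#' @param alpha Threshold on the Fisher-z difference p-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.utr_cor <- function(object, alpha = 0.05, ...) {
  conditions <- attr(object, "conditions")
  df <- as_tibble(unclass_utr_cor(object))
  df$significant_difference <- !is.na(df$p_diff) & df$p_diff < alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[paste0("rho_", conditions[1])]],
    y = .data[[paste0("rho_", conditions[2])]],
    colour = .data$significant_difference)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$klass)) +
    ggplot2::labs(x = paste("Spearman rho,", conditions[1]),
                  y = paste("Spearman rho,", conditions[2]),
                  colour = paste0("p_diff < ", alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
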