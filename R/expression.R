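#' Build a quantification table with gene totals and isoform fractions
#'
#' Derives per-gene TPM totals (sum of member transcripts) and per-transcript
#' expression fractions (transcript TPM / gene TPM) from a transcript-level
#' TPM matrix. Fractions are missing where the gene total is zero.
#'
#' @param tpm Wide tibble: a `transcript_id` column plus one numeric column
#'   per sample.
#' @param tx2gene Tibble mapping `transcript_id` to `gene_id`.
#' @return A tibble of class `quant_table`, long format: `transcript_id`,
#'   `gene_id`, `sample`, `tpm`, `gene_tpm`, `fraction`.
#' @export
quant_table <- function(tpm, tx2gene) {
  stopifnot(is.data.frame(tpm), "transcript_id" %in% names(tpm))
  missing_map <- setdiff(tpm$transcript_id, tx2gene$transcript_id)
  if (length(missing_map) > 0) {
    abort(paste0("transcripts without a gene mapping: ",
                 paste(missing_map, collapse = ", ")),
          class = "utrintrons_lookup_error")
  }
  long <- tidyr::pivot_longer(tpm, -"transcript_id", names_to = "sample",
                              values_to = "tpm")
  if (any(long$tpm < 0)) {
    abort("TPM values must be non-negative",
          class = "utrintrons_validation_error")
  }
  long <- left_join(long, tx2gene[, c("transcript_id", "gene_id")],
                    by = "transcript_id")
  long <- long |>
    group_by(.data$gene_id, .data$sample) |>
    mutate(gene_tpm = sum(.data$tpm)) |>
    ungroup() |>
    mutate(fraction = ifelse(.data$gene_tpm > 0, .data$tpm / .data$gene_tpm,
                             NA_real_)) |>
    select("transcript_id", "gene_id", "sample", "tpm", "gene_tpm",
           "fraction")
  class(long) <- c("quant_table", class(long))
  long
}

#' Expression fraction of a transcript in a sample
#'
#' @param q A `quant_table`.
#' @param transcript Transcript identifier.
#' @param sample Sample name.
#' @return Transcript TPM / gene TPM, or `NA` where the gene total is zero.
#' @export
fraction_expression <- function(q, transcript, sample) {
  row <- q[q$transcript_id == transcript & q$sample == sample, ]
  if (nrow(row) == 0) {
    abort(paste0("unknown transcript/sample: ", transcript, " / ", sample),
          class = "utrintrons_lookup_error")
  }
  row$fraction[[1]]
}

#' Per-sample expressed calls
#'
#' A transcript is called expressed in a sample when its TPM exceeds
#' `min_tpm` and its expression fraction exceeds `min_fraction`, both
#' strictly.
#'
#' @param q A `quant_table`.
#' @param transcript Optional transcript identifier; when given with `sample`
#'   the call is returned as a logical scalar.
#' @param sample Optional sample name.
#' @param min_tpm Strict TPM threshold (default 1).
#' @param min_fraction Strict transcript/gene fraction threshold (default
#'   0.25).
#' @return Either a logical scalar, or the `quant_table` with an `expressed`
#'   column added.
#' @export
is_expressed <- function(q, transcript = NULL, sample = NULL, min_tpm = 1.0,
                         min_fraction = 0.25) {
  calls <- q$tpm > min_tpm & !is.na(q$fraction) & q$fraction > min_fraction
  if (!is.null(transcript) && !is.null(sample)) {
    i <- which(q$transcript_id == transcript & q$sample == sample)
    if (length(i) == 0) {
      abort(paste0("unknown transcript/sample: ", transcript, " / ", sample),
            class = "utrintrons_lookup_error")
    }
    return(calls[[i[1]]])
  }
  q$expressed <- calls
  q
}

#' Junctions of transcripts
#'
#' Convenience wrapper over [transcript_introns()] keyed for joining against
#' junction-count tables.
#'
#' @param models Transcript model tibble.
#' @return Tibble `transcript_id`, `chrom`, `strand`, `start`, `end`.
#' @export
transcript_junctions <- function(models) {
  ti <- transcript_introns(models)
  tibble(transcript_id = ti$transcript_id, chrom = ti$chrom,
         strand = ti$strand, start = ti$intron_start, end = ti$intron_end)
}

#' Broadly-expressed calls with junction coverage evidence
#'
#' A transcript is broadly expressed when it is expressed (strict TPM and
#' fraction thresholds) in at least `min_sample_frac` of the samples of one
#' condition (count threshold taken as the ceiling), and every one of its
#' junctions has at least one supporting read summed across all samples.
#' Junctions absent from the count table count as uncovered.
#'
#' @param q A `quant_table`.
#' @param junction_counts Wide tibble: `chrom`, `strand`, `start`, `end` plus
#'   one numeric column per sample.
#' @param tx_junctions Tibble from [transcript_junctions()] for the
#'   transcripts of interest.
#' @param sample_sheet Tibble `sample`, `condition`; every sample in `q` must
#'   be labelled.
#' @param min_tpm,min_fraction Strict expression thresholds.
#' @param min_sample_frac Fraction of a condition's samples required
#'   (default 0.10).
#' @return Tibble with one row per transcript: per-condition expressed
#'   fractions (`frac_<condition>`), `junctions_covered` and
#'   `broadly_expressed`.
#' @export
broadly_expressed <- function(q, junction_counts, tx_junctions, sample_sheet,
                              min_tpm = 1.0, min_fraction = 0.25,
                              min_sample_frac = 0.10) {
  unlabelled <- setdiff(unique(q$sample), sample_sheet$sample)
  if (length(unlabelled) > 0) {
    abort(paste0("samples without a condition label: ",
                 paste(unlabelled, collapse = ", ")),
          class = "utrintrons_lookup_error")
  }
  calls <- is_expressed(q, min_tpm = min_tpm, min_fraction = min_fraction)
  calls <- left_join(calls, sample_sheet, by = "sample")
  cond_sizes <- table(sample_sheet$condition[
    sample_sheet$sample %in% unique(q$sample)])
  per_cond <- calls |>
    group_by(.data$transcript_id, .data$condition) |>
    summarise(n_expressed = sum(.data$expressed), .groups = "drop")
  per_cond$n_cond <- as.integer(cond_sizes[per_cond$condition])
  per_cond$frac <- per_cond$n_expressed / per_cond$n_cond
  per_cond$meets <- per_cond$n_expressed >=
    ceiling(min_sample_frac * per_cond$n_cond)
  wide <- tidyr::pivot_wider(
    per_cond[, c("transcript_id", "condition", "frac")],
    names_from = "condition", values_from = "frac", names_prefix = "frac_")
  meets_any <- per_cond |>
    group_by(.data$transcript_id) |>
    summarise(meets_frac = any(.data$meets), .groups = "drop")

  jc_samples <- setdiff(names(junction_counts),
                        c("chrom", "strand", "start", "end"))
  jc <- junction_counts
  jc$total <- rowSums(as.matrix(jc[, jc_samples, drop = FALSE]))
  cov <- left_join(tx_junctions, jc[, c("chrom", "strand", "start", "end",
                                        "total")],
                   by = c("chrom", "strand", "start", "end"))
  cov$total[is.na(cov$total)] <- 0
  covered <- cov |>
    group_by(.data$transcript_id) |>
    summarise(junctions_covered = all(.data$total >= 1), .groups = "drop")

  out <- left_join(wide, meets_any, by = "transcript_id")
  out <- left_join(out, covered, by = "transcript_id")
  # transcripts with no junctions satisfy the coverage clause vacuously
  out$junctions_covered[is.na(out$junctions_covered)] <- TRUE
  out$broadly_expressed <- out$meets_frac & out$junctions_covered
  select(out, -"meets_frac")
}
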