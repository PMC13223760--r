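#' Classify how assembled transcripts overlap the reference
#'
#' Assigns each query transcript one of six categories relative to a reference
#' set: `identical` (exon chain equals a reference), `fragment` (contiguous
#' sub-chain of a reference with matching internal junctions and boundary
#' exons contained in the reference's exons; a junction-less query must also
#' touch the reference CDS span, otherwise the containment categories below
#' apply), `contained_intronic` (whole span
#' inside one reference intron), `contained_utr` (whole span inside a
#' reference 5' or 3' UTR region), `intergenic` (no exonic overlap with any
#' reference on either strand), and `overlapping_novel` otherwise. When
#' several references give different verdicts the most permissive wins:
#' identical > fragment > overlapping_novel > contained_utr >
#' contained_intronic > intergenic. Identity and fragment tests require the
#' same strand; containment and overlap tests do not.
#'
#' @param queries,refs Transcript model tibbles.
#' @return A tibble `transcript_id`, `category`.
#' @export
overlap_class <- function(queries, refs) {
  precedence <- c(identical = 6, fragment = 5, overlapping_novel = 4,
                  contained_utr = 3, contained_intronic = 2, intergenic = 1)
  cats <- vapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    near <- refs[refs$chrom == q$chrom &
                   refs$tx_start < q$tx_end & q$tx_start < refs$tx_end, ,
                 drop = FALSE]
    if (nrow(near) == 0) return("intergenic")
    best <- "intergenic"
    for (j in seq_len(nrow(near))) {
      v <- pairwise_overlap_class(q, near[j, ])
      if (precedence[[v]] > precedence[[best]]) best <- v
      if (best == "identical") break
    }
    best
  }, character(1))
  tibble(transcript_id = queries$transcript_id, category = cats)
}

pairwise_overlap_class <- function(q, r) {
  qe <- q$exons[[1]]
  re <- r$exons[[1]]
  same_strand <- q$strand == r$strand
  if (same_strand && identical_chain(qe, re)) return("identical")
  if (same_strand && is_fragment(qe, re)) {
    # a junction-less query wholly within a coding reference's UTR is a UTR
    # containment, not a fragment of the transcript
    in_cds <- is.na(r$cds_start) ||
      (q$tx_start < r$cds_end && r$cds_start < q$tx_end)
    if (nrow(qe) > 1 || in_cds) return("fragment")
  }
  rim <- intron_mat(re)
  if (nrow(rim) > 0 &&
      any(rim[, 1] <= q$tx_start & q$tx_end <= rim[, 2])) {
    return("contained_intronic")
  }
  if (!is.na(r$cds_start) && !is.na(r$stop_start)) {
    if (r$strand == "+") {
      utr5 <- c(r$tx_start, r$cds_start)
      utr3 <- c(r$stop_end, r$tx_end)
    } else {
      utr5 <- c(r$cds_end, r$tx_end)
      utr3 <- c(r$tx_start, r$stop_start)
    }
    in_span <- function(span) {
      span[2] > span[1] && span[1] <= q$tx_start && q$tx_end <= span[2]
    }
    if (in_span(utr5) || in_span(utr3)) return("contained_utr")
  }
  if (exonic_overlap(qe, re)) return("overlapping_novel")
  "intergenic"
}

identical_chain <- function(a, b) {
  nrow(a) == nrow(b) && all(a == b)
}

# Query introns must form a contiguous run of the reference introns, with the
# query's terminal exons contained in the flanking reference exons.
is_fragment <- function(qe, re) {
  qim <- intron_mat(qe)
  rim <- intron_mat(re)
  if (nrow(qim) == 0) {
    return(any(re[, 1] <= qe[1, 1] & qe[1, 2] <= re[, 2]))
  }
  if (nrow(rim) < nrow(qim)) return(FALSE)
  k <- nrow(qim)
  for (j in seq_len(nrow(rim) - k + 1)) {
    run <- rim[j:(j + k - 1), , drop = FALSE]
    if (all(run == qim)) {
      first_ok <- qe[1, 1] >= re[j, 1]
      last_ok <- qe[nrow(qe), 2] <= re[j + k, 2]
      if (first_ok && last_ok) return(TRUE)
    }
  }
  FALSE
}

exonic_overlap <- function(a, b) {
  for (i in seq_len(nrow(a))) {
    if (any(b[, 1] < a[i, 2] & a[i, 1] < b[, 2])) return(TRUE)
  }
  FALSE
}

#' Apply the merge-stage assembly filters
#'
#' Removes assembled transcripts that are fragments of reference transcripts,
#' contained entirely within reference introns or UTRs, or intergenic, and
#' requires an expression level above `min_tpm` (strict) in at least one
#' sample. Only `identical` and `overlapping_novel` transcripts survive.
#'
#' @param queries Transcript model tibble for the assembly.
#' @param refs Reference transcript model tibble.
#' @param tpm Wide tibble with a `transcript_id` column and one numeric column
#'   per sample.
#' @param min_tpm Strict TPM threshold (default 1).
#' @return The filtered subset of `queries`, with the verdict table attached
#'   as attribute `"verdicts"`.
#' @export
apply_merge_filters <- function(queries, refs, tpm, min_tpm = 1.0) {
  missing_tx <- setdiff(queries$transcript_id, tpm$transcript_id)
  if (length(missing_tx) > 0) {
    abort(paste0("transcripts absent from the TPM table: ",
                 paste(missing_tx, collapse = ", ")),
          class = "utrintrons_lookup_error")
  }
  verdicts <- overlap_class(queries, refs)
  sample_cols <- setdiff(names(tpm), "transcript_id")
  max_tpm <- apply(as.matrix(tpm[, sample_cols, drop = FALSE]), 1, max)
  names(max_tpm) <- tpm$transcript_id
  keep_cat <- verdicts$category %in% c("identical", "overlapping_novel")
  keep_tpm <- max_tpm[queries$transcript_id] > min_tpm
  out <- queries[keep_cat & keep_tpm, , drop = FALSE]
  attr(out, "verdicts") <- verdicts
  out
}
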