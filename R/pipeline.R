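#' End-to-end 3UI annotation workflow
#'
#' Runs the full detection workflow on file inputs: read the reference and
#' assembly GTFs, curate the high-confidence reference set, build the
#' boundary/junction indices, apply the merge-stage assembly filters (when a
#' TPM table is supplied), classify 3UIs, and (when a genome is supplied)
#' append sequence features.
#'
#' @param reference_gtf Path to the reference annotation GTF.
#' @param assembly_gtf Path to the query assembly GTF (exon features).
#' @param genome_fasta Optional genome FASTA path for sequence features.
#' @param tpm_tsv Optional transcript x sample TPM TSV (column
#'   `transcript_id` plus samples); enables the merge filters.
#' @param min_tpm Strict TPM threshold for the merge filter.
#' @param max_tsl Maximum transcript support level for the reference
#'   curation.
#' @return A list with `records` (tibble, including a `skipped` attribute),
#'   `indices`, `refs_hc`, `assembly` (post-filter models) and `verdicts`
#'   (overlap categories, when filtering ran).
#' @export
annotate_utr_introns <- function(reference_gtf, assembly_gtf,
                                 genome_fasta = NULL, tpm_tsv = NULL,
                                 min_tpm = 1.0, max_tsl = 2) {
  refs <- transcript_models(read_gtf(reference_gtf))
  queries <- transcript_models(read_gtf(assembly_gtf))
  refs_hc <- filter_high_confidence(refs, max_tsl = max_tsl)
  indices <- reference_indices(refs, refs_hc)
  verdicts <- NULL
  if (!is.null(tpm_tsv)) {
    tpm <- read_tsv_plain(tpm_tsv)
    queries <- apply_merge_filters(queries, refs, tpm, min_tpm = min_tpm)
    verdicts <- attr(queries, "verdicts")
  }
  records <- classify_utr_introns(queries, refs_hc, indices)
  if (!is.null(genome_fasta)) {
    genome <- read_genome(genome_fasta)
    records_attr <- attr(records, "skipped")
    records <- add_intron_features(records, genome)
    attr(records, "skipped") <- records_attr
  }
  list(records = records, indices = indices, refs_hc = refs_hc,
       assembly = queries, verdicts = verdicts)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE,
                              comment.char = "#"))
}
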