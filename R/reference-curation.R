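#' Select high-confidence reference transcripts
#'
#' Keeps transcripts whose transcript support level (TSL) is numeric and at
#' most `max_tsl`, and whose APPRIS tag is one of the allowed classes.
#' Transcripts lacking either attribute, or with a non-numeric TSL (e.g.
#' `"NA"`), are excluded.
#'
#' @param refs Transcript model tibble.
#' @param max_tsl Maximum transcript support level retained (default 2).
#' @param appris_allowed Character vector of allowed APPRIS classes; a
#'   transcript's tag matches when it starts with one of these (so
#'   `appris_principal_1` matches `appris_principal`).
#' @return The subset of `refs` passing both filters.
#' @export
filter_high_confidence <- function(refs, max_tsl = 2,
                                   appris_allowed = c("appris_principal",
                                                      "appris_alternative_1",
                                                      "appris_alternative_2")) {
  tsl_num <- suppressWarnings(as.integer(stringr::str_extract(refs$tsl,
                                                              "^[0-9]+")))
  tsl_ok <- !is.na(tsl_num) & tsl_num <= max_tsl
  appris_ok <- !is.na(refs$appris) &
    map_lgl(refs$appris, function(a) any(startsWith(a, appris_allowed)))
  refs[tsl_ok & appris_ok, , drop = FALSE]
}

#' Build the reference boundary and junction indices
#'
#' From the full reference annotation, collects (i) `coding_boundaries`: the
#' donor and acceptor positions of every intron lying between the start codon
#' and the stop codon of a coding reference transcript (transcript order), and
#' (ii) `all_junctions`: every intron of every reference transcript. These
#' indices drive the e3UI/co3UI call and the novelty call respectively.
#'
#' @param refs_full Transcript model tibble for the complete reference
#'   annotation.
#' @param refs_hc High-confidence subset from [filter_high_confidence()];
#'   defaults to computing it from `refs_full`.
#' @param include_utr5 Should introns wholly within the 5' UTR count as coding
#'   boundaries? Default `FALSE`: the boundary set is restricted to introns
#'   between the start and stop codons.
#' @return An object of class `reference_indices`: a list with tibbles
#'   `coding_boundaries` (`chrom`, `strand`, `pos`, `side`), `all_junctions`
#'   (`chrom`, `strand`, `start`, `end`) and the character vector
#'   `high_confidence_ids`.
#' @export
reference_indices <- function(refs_full, refs_hc = filter_high_confidence(refs_full),
                              include_utr5 = FALSE) {
  junctions <- transcript_introns(refs_full)
  all_junctions <- distinct(junctions[, c("chrom", "strand", "intron_start",
                                          "intron_end")])
  names(all_junctions) <- c("chrom", "strand", "start", "end")

  boundary_rows <- pmap(refs_full, function(transcript_id, chrom, strand,
                                            exons, cds_start, cds_end,
                                            stop_start, stop_end, ...) {
    if (is.na(cds_start)) return(NULL)
    if (is.na(stop_start)) {
      warn(paste0("reference transcript ", transcript_id,
                  " has a CDS but no derivable stop codon; ",
                  "skipped for coding boundaries"))
      return(NULL)
    }
    im <- intron_mat(exons)
    if (nrow(im) == 0) return(NULL)
    if (strand == "+") {
      lo <- if (include_utr5) -Inf else cds_start
      coding <- im[, 1] >= lo & im[, 2] <= stop_end
      donors <- im[coding, 1]
      acceptors <- im[coding, 2]
    } else {
      hi <- if (include_utr5) Inf else cds_end
      coding <- im[, 1] >= stop_start & im[, 2] <= hi
      donors <- im[coding, 2]
      acceptors <- im[coding, 1]
    }
    if (length(donors) == 0) return(NULL)
    tibble(
      chrom = chrom, strand = strand,
      pos = as.integer(c(donors, acceptors)),
      side = rep(c("donor", "acceptor"), times = c(length(donors),
                                                   length(acceptors)))
    )
  })
  coding_boundaries <- distinct(bind_rows(boundary_rows))
  if (nrow(coding_boundaries) == 0) {
    coding_boundaries <- tibble(chrom = character(0), strand = character(0),
                                pos = integer(0), side = character(0))
  }
  structure(
    list(coding_boundaries = coding_boundaries,
         all_junctions = all_junctions,
         high_confidence_ids = refs_hc$transcript_id),
    class = "reference_indices"
  )
}

#' @export
print.reference_indices <- function(x, ...) {
  cat("<reference_indices>\n")
  cat("  coding boundaries:", nrow(x$coding_boundaries), "\n")
  cat("  reference junctions:", nrow(x$all_junctions), "\n")
  cat("  high-confidence transcripts:", length(x$high_confidence_ids), "\n")
  invisible(x)
}

boundary_keys <- function(chrom, strand, pos, side) {
  paste(chrom, strand, pos, side, sep = "\r")
}

junction_keys <- function(chrom, strand, start, end) {
  paste(chrom, strand, start, end, sep = "\r")
}

#' Export reference indices
#'
#' Writes coding boundaries as BED6 (side in the name column) and junctions as
#' TSV.
#'
#' @param indices A `reference_indices` object.
#' @param boundaries_bed,junctions_tsv Output paths (either may be `NULL`).
#' @return `indices`, invisibly.
#' @export
write_indices <- function(indices, boundaries_bed = NULL, junctions_tsv = NULL) {
  if (!is.null(boundaries_bed)) {
    b <- indices$coding_boundaries
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", b$chrom, b$pos, b$pos + 1L,
                       b$side, b$strand), boundaries_bed)
  }
  if (!is.null(junctions_tsv)) {
    write.table(indices$all_junctions, junctions_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(indices)
}
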