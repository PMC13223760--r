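#' Read a GTF file into a tidy feature table
#'
#' Parses an Ensembl-dialect GTF file and returns one row per feature with
#' 0-based half-open coordinates. Attribute keys commonly used downstream
#' (`transcript_id`, `gene_id`, `transcript_support_level`, `tag`,
#' `transcript_biotype`/`gene_biotype`) are lifted into columns when present.
#'
#' @param path Path to a GTF file (plain text, tab-delimited, 9 columns).
#' @param features Character vector of feature types to keep. Defaults to the
#'   types used by transcript models.
#'
#' @return A tibble with columns `chrom`, `feature`, `start`, `end` (0-based
#'   half-open), `strand`, plus available attribute columns.
#' @export
read_gtf <- function(path,
                     features = c("exon", "CDS", "stop_codon", "start_codon")) {
  if (!file.exists(path)) {
    abort(paste0("GTF file not found: ", path), class = "utrintrons_io_error")
  }
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  tbl <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    feature = as.character(gr$type),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  for (col in c("transcript_id", "gene_id", "transcript_support_level",
                "tag", "transcript_biotype", "gene_biotype")) {
    if (col %in% names(mc)) {
      v <- mc[[col]]
      if (is.list(v)) v <- map_chr(v, function(x) paste(x, collapse = ","))
      tbl[[col]] <- as.character(v)
    }
  }
  tbl <- tbl[tbl$feature %in% features, , drop = FALSE]
  as_tibble(tbl)
}

# Cheap structural scan so malformed lines are reported with their line number
# (the downstream importer fails with an opaque message otherwise).
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  bad <- which(body)[nfield != 9L]
  if (length(bad) > 0) {
    abort(
      paste0("malformed GTF line ", bad[1], " in ", path,
             ": expected 9 tab-separated fields, found ", nfield[match(bad[1], which(body))]),
      class = "utrintrons_parse_error"
    )
  }
  invisible(TRUE)
}

#' Write transcript models to a GTF file
#'
#' Emits `exon`, `CDS` and `stop_codon` features (where present) with
#' Ensembl-style attributes, converting internal 0-based half-open coordinates
#' back to 1-based inclusive GTF coordinates.
#'
#' @param models A transcript model tibble from [transcript_models()].
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "utrintrons") {
  rows <- pmap(models, function(transcript_id, gene_id, chrom, strand, exons,
                                cds, stop_start, stop_end, tsl, appris,
                                biotype, ...) {
    attr_tail <- ""
    if (!is.na(tsl)) {
      attr_tail <- paste0(attr_tail, ' transcript_support_level "', tsl, '";')
    }
    if (!is.na(appris)) {
      attr_tail <- paste0(attr_tail, ' tag "', appris, '";')
    }
    if (!is.na(biotype)) {
      attr_tail <- paste0(attr_tail, ' transcript_biotype "', biotype, '";')
    }
    base_attr <- paste0('gene_id "', gene_id, '"; transcript_id "',
                        transcript_id, '";', attr_tail)
    fmt <- function(feature, s, e, frame = ".") {
      paste(chrom, source, feature, s + 1L, e, ".", strand, frame, base_attr,
            sep = "\t")
    }
    out <- fmt("exon", exons[, 1], exons[, 2])
    if (!is.null(cds) && nrow(cds) > 0) {
      out <- c(out, fmt("CDS", cds[, 1], cds[, 2], "0"))
    }
    if (!is.na(stop_start)) {
      out <- c(out, fmt("stop_codon", stop_start, stop_end, "0"))
    }
    out
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Export transcripts as BED12
#'
#' @param models Transcript model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_bed <- function(models, path) {
  lines <- pmap_chr_models(models, function(row) {
    ex <- row$exons[[1]]
    starts <- ex[, 1] - row$tx_start
    sizes <- ex[, 2] - ex[, 1]
    thick_s <- if (is.na(row$cds_start)) row$tx_start else row$cds_start
    thick_e <- if (is.na(row$cds_end)) row$tx_start else row$cds_end
    paste(row$chrom, row$tx_start, row$tx_end, row$transcript_id, 0,
          row$strand, thick_s, thick_e, "0,0,0", nrow(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Export 3UI records as BED6
#'
#' One line per record; `name` is `transcript|class|novelty` and `score` is the
#' spliced distance to the stop codon.
#'
#' @param records Record tibble from [classify_utr_introns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_bed <- function(records, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s",
    records$chrom, records$intron_start, records$intron_end,
    paste(records$transcript_id, records$klass,
          ifelse(records$novel, "novel", "annotated"), sep = "|"),
    records$distance_to_stop, records$strand
  )
  writeLines(lines, path)
  invisible(path)
}

pmap_chr_models <- function(models, f) {
  vapply(seq_len(nrow(models)), function(i) f(models[i, ]), character(1))
}
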