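#' Build transcript models from a GTF feature table
#'
#' Collapses per-feature rows into one row per transcript, with exons stored
#' as a sorted two-column matrix of 0-based half-open intervals, the CDS and
#' stop codon reduced to genomic spans, and confidence attributes (transcript
#' support level, APPRIS tag) lifted out of the attribute strings. When a
#' transcript has a CDS but no explicit `stop_codon` feature, the stop codon
#' is derived by walking three exonic bases transcript-downstream of the CDS
#' 3' end (Ensembl dialect: the CDS excludes the stop codon).
#'
#' @param features A tidy feature tibble from [read_gtf()].
#'
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exons` (list of matrices), `cds` (list of matrices or
#'   `NULL`), `n_exons`, `tx_start`, `tx_end`, `cds_start`, `cds_end`,
#'   `stop_start`, `stop_end`, `stop_split`, `tsl`, `appris`, `biotype`.
#' @export
transcript_models <- function(features) {
  stopifnot(is.data.frame(features))
  needed <- c("chrom", "feature", "start", "end", "strand", "transcript_id",
              "gene_id")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (opt in c("transcript_support_level", "tag", "transcript_biotype")) {
    if (!opt %in% names(features)) features[[opt]] <- NA_character_
  }
  pieces <- split(features, features$transcript_id)
  rows <- lapply(pieces, build_one_model)
  out <- bind_rows(rows)
  out <- out[order(out$transcript_id), , drop = FALSE]
  attr(out, "utrintrons_models") <- TRUE
  out
}

build_one_model <- function(ft) {
  tid <- ft$transcript_id[[1]]
  if (length(unique(ft$chrom)) != 1L || length(unique(ft$strand)) != 1L) {
    abort(paste0("transcript ", tid,
                 " has inconsistent chromosome or strand among its features"),
          class = "utrintrons_validation_error")
  }
  strand <- ft$strand[[1]]
  if (!strand %in% c("+", "-")) {
    abort(paste0("transcript ", tid, " has unstranded features"),
          class = "utrintrons_validation_error")
  }
  ex <- ft[ft$feature == "exon", , drop = FALSE]
  if (nrow(ex) == 0) {
    abort(paste0("transcript ", tid, " has no exon features"),
          class = "utrintrons_validation_error")
  }
  exons <- cbind(ex$start, ex$end)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 1] >= exons[, 2])) {
    abort(paste0("transcript ", tid, " has an empty or inverted exon"),
          class = "utrintrons_validation_error")
  }
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    abort(paste0("transcript ", tid, " has overlapping exons"),
          class = "utrintrons_validation_error")
  }

  cds_rows <- ft[ft$feature == "CDS", , drop = FALSE]
  cds <- NULL
  cds_start <- NA_integer_
  cds_end <- NA_integer_
  if (nrow(cds_rows) > 0) {
    cds <- cbind(cds_rows$start, cds_rows$end)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    contained <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(contained)) {
      abort(paste0("transcript ", tid, " has CDS outside its exons"),
            class = "utrintrons_validation_error")
    }
    cds_start <- as.integer(cds[1, 1])
    cds_end <- as.integer(cds[nrow(cds), 2])
  }

  sc_rows <- ft[ft$feature == "stop_codon", , drop = FALSE]
  stop_start <- NA_integer_
  stop_end <- NA_integer_
  stop_split <- FALSE
  if (nrow(sc_rows) > 0) {
    stop_start <- as.integer(min(sc_rows$start))
    stop_end <- as.integer(max(sc_rows$end))
    stop_split <- sum(sc_rows$end - sc_rows$start) < (stop_end - stop_start)
  } else if (!is.na(cds_start)) {
    sc <- tryCatch(derive_stop_codon(exons, strand, cds_start, cds_end),
                   error = function(e) NULL)
    if (!is.null(sc)) {
      stop_start <- sc$start
      stop_end <- sc$end
      stop_split <- sc$split
    }
  }

  appris <- NA_character_
  tags <- ft$tag[!is.na(ft$tag)]
  if (length(tags) > 0) {
    hit <- stringr::str_extract(tags, "appris_[a-z]+(_[0-9]+)?")
    hit <- hit[!is.na(hit)]
    if (length(hit) > 0) appris <- hit[[1]]
  }
  tsl_raw <- ft$transcript_support_level[!is.na(ft$transcript_support_level)]
  tsl <- if (length(tsl_raw) > 0) tsl_raw[[1]] else NA_character_
  bio_raw <- ft$transcript_biotype[!is.na(ft$transcript_biotype)]
  biotype <- if (length(bio_raw) > 0) bio_raw[[1]] else NA_character_

  n_ex <- nrow(exons)
  tx_start <- as.integer(exons[1, 1])
  tx_end <- as.integer(exons[n_ex, 2])
  tibble(
    transcript_id = tid,
    gene_id = ft$gene_id[[1]],
    chrom = ft$chrom[[1]],
    strand = strand,
    exons = list(exons),
    cds = list(cds),
    n_exons = n_ex,
    tx_start = tx_start,
    tx_end = tx_end,
    cds_start = cds_start,
    cds_end = cds_end,
    stop_start = stop_start,
    stop_end = stop_end,
    stop_split = stop_split,
    tsl = tsl,
    appris = appris,
    biotype = biotype
  )
}

# Walk `n` exonic bases transcript-downstream of the CDS 3' end. Returns the
# genomic span of the walked bases plus a flag for spans crossing an exon
# junction. Errors when fewer than `n` exonic bases remain.
derive_stop_codon <- function(exons, strand, cds_start, cds_end, n = 3L) {
  positions <- integer(0)
  if (strand == "+") {
    p <- cds_end
    for (i in seq_len(nrow(exons))) {
      if (exons[i, 2] <= p) next
      from <- max(p, exons[i, 1])
      take <- seq.int(from, exons[i, 2] - 1L)
      positions <- c(positions, take)
      if (length(positions) >= n) break
    }
  } else {
    p <- cds_start - 1L
    for (i in rev(seq_len(nrow(exons)))) {
      if (exons[i, 1] > p) next
      to <- min(p, exons[i, 2] - 1L)
      take <- seq.int(to, exons[i, 1])
      positions <- c(positions, take)
      if (length(positions) >= n) break
    }
  }
  if (length(positions) < n) {
    abort("fewer than 3 exonic bases downstream of the CDS; cannot derive stop codon",
          class = "utrintrons_stop_error")
  }
  positions <- positions[seq_len(n)]
  span_start <- min(positions)
  span_end <- max(positions) + 1L
  list(start = as.integer(span_start), end = as.integer(span_end),
       split = (span_end - span_start) > n)
}

#' Stop codon interval of one transcript
#'
#' Returns the explicit `stop_codon` feature when present, otherwise the
#' interval derived from the CDS 3' end by an exonic walk.
#'
#' @param models Transcript model tibble.
#' @param transcript_id Transcript identifier.
#' @return A list with `start`, `end` (0-based half-open genomic span) and
#'   `split` (whether the codon crosses an exon junction).
#' @export
stop_codon_of <- function(models, transcript_id) {
  row <- model_row(models, transcript_id)
  if (is.na(row$stop_start)) {
    if (is.na(row$cds_start)) {
      abort(paste0("transcript ", transcript_id,
                   " has neither a stop_codon feature nor a CDS"),
            class = "utrintrons_stop_error")
    }
    sc <- derive_stop_codon(row$exons[[1]], row$strand, row$cds_start,
                            row$cds_end)
    return(sc)
  }
  list(start = row$stop_start, end = row$stop_end, split = row$stop_split)
}

# Gaps between consecutive sorted exons as a two-column matrix.
intron_mat <- function(exons) {
  n <- nrow(exons)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cbind(exons[-n, 2], exons[-1, 1])
}

#' Introns of transcripts
#'
#' Derives the intron chain (gaps between consecutive exons) for every
#' transcript in a model table. Donor and acceptor positions are strand-aware:
#' the donor is the transcript-5' boundary of the intron and the acceptor the
#' transcript-3' boundary.
#'
#' @param models Transcript model tibble.
#' @return A tibble with one row per intron: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `intron_start`, `intron_end`, `donor_pos`,
#'   `acceptor_pos`. Single-exon transcripts contribute no rows.
#' @export
transcript_introns <- function(models) {
  rows <- pmap(models, function(transcript_id, gene_id, chrom, strand, exons,
                                ...) {
    im <- intron_mat(exons)
    if (nrow(im) == 0) return(NULL)
    donor <- as.integer(if (strand == "+") im[, 1] else im[, 2])
    acceptor <- as.integer(if (strand == "+") im[, 2] else im[, 1])
    tibble(
      transcript_id = transcript_id,
      gene_id = gene_id,
      chrom = chrom,
      strand = strand,
      intron_start = as.integer(im[, 1]),
      intron_end = as.integer(im[, 2]),
      donor_pos = donor,
      acceptor_pos = acceptor
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(transcript_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  intron_start = integer(0), intron_end = integer(0),
                  donor_pos = integer(0), acceptor_pos = integer(0))
  }
  out
}

#' Spliced (exonic) distance between two positions of a transcript
#'
#' Counts the exonic bases between genomic positions `a` and `b` along the
#' mature transcript, excluding intron lengths. Symmetric in `a` and `b`.
#'
#' @param models Transcript model tibble.
#' @param transcript_id Transcript identifier.
#' @param a,b 0-based genomic positions, each falling inside an exon.
#' @return Integer count of exonic bases in `[min(a,b), max(a,b))`.
#' @export
spliced_distance <- function(models, transcript_id, a, b) {
  row <- model_row(models, transcript_id)
  exons <- row$exons[[1]]
  for (p in c(a, b)) {
    if (!any(exons[, 1] <= p & p < exons[, 2])) {
      abort(paste0("position ", p, " is not exonic in transcript ",
                   transcript_id),
            class = "utrintrons_coordinate_error")
    }
  }
  exonic_bases_between(exons, min(a, b), max(a, b))
}

# Number of exonic bases in the genomic interval [lo, hi).
exonic_bases_between <- function(exons, lo, hi) {
  if (hi <= lo) return(0L)
  ov <- pmin(exons[, 2], hi) - pmax(exons[, 1], lo)
  as.integer(sum(ov[ov > 0]))
}

model_row <- function(models, transcript_id) {
  i <- match(transcript_id, models$transcript_id)
  if (is.na(i)) {
    abort(paste0("unknown transcript: ", transcript_id),
          class = "utrintrons_lookup_error")
  }
  models[i, ]
}
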