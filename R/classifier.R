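#' Candidate references for a query transcript
#'
#' References (from the high-confidence set) on the same chromosome and strand
#' whose start codon's first base, in transcript order, lies within an exon of
#' the query.
#'
#' @param models Query transcript model tibble.
#' @param transcript_id Query transcript identifier.
#' @param refs_hc High-confidence reference model tibble (must carry CDS and a
#'   derivable stop codon).
#' @return The subset of `refs_hc` that are candidates.
#' @export
candidate_references <- function(models, transcript_id, refs_hc) {
  q <- model_row(models, transcript_id)
  candidate_refs_row(q, refs_hc)
}

candidate_refs_row <- function(q, refs_hc) {
  cand <- refs_hc[refs_hc$chrom == q$chrom & refs_hc$strand == q$strand &
                    !is.na(refs_hc$cds_start) & !is.na(refs_hc$stop_start), ,
                  drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  exons <- q$exons[[1]]
  start_base <- ifelse(cand$strand == "+", cand$cds_start, cand$cds_end - 1L)
  inside <- vapply(start_base, function(p) {
    any(exons[, 1] <= p & p < exons[, 2])
  }, logical(1))
  cand[inside, , drop = FALSE]
}

#' Does a query share the reference's intron chain over its CDS span?
#'
#' The set of query introns whose genomic span lies entirely within the
#' reference's CDS genomic span must equal, as exact coordinate pairs, the set
#' of reference introns within that same span.
#'
#' @param models Query transcript model tibble.
#' @param transcript_id Query transcript identifier.
#' @param refs Reference model tibble.
#' @param ref_id Reference transcript identifier.
#' @return Logical scalar.
#' @export
cds_chain_match <- function(models, transcript_id, refs, ref_id) {
  q <- model_row(models, transcript_id)
  r <- model_row(refs, ref_id)
  cds_chain_match_rows(q, r)
}

cds_chain_match_rows <- function(q, r) {
  if (is.na(r$cds_start)) {
    abort(paste0("reference ", r$transcript_id, " has no CDS"),
          class = "utrintrons_validation_error")
  }
  qin <- introns_within(intron_mat(q$exons[[1]]), r$cds_start, r$cds_end)
  rin <- introns_within(intron_mat(r$exons[[1]]), r$cds_start, r$cds_end)
  identical_chain(qin, rin)
}

introns_within <- function(im, lo, hi) {
  if (nrow(im) == 0) return(im)
  im[im[, 1] >= lo & im[, 2] <= hi, , drop = FALSE]
}

#' Query introns downstream of a reference stop codon
#'
#' Introns of the query whose donor lies strictly transcript-downstream of the
#' last base of the reference's stop codon, ordered 5' to 3' along the
#' transcript.
#'
#' @inheritParams cds_chain_match
#' @return Matrix of intron intervals (0-based half-open), possibly empty.
#' @export
utr_introns <- function(models, transcript_id, refs, ref_id) {
  q <- model_row(models, transcript_id)
  r <- model_row(refs, ref_id)
  utr_introns_rows(q, r)
}

utr_introns_rows <- function(q, r) {
  im <- intron_mat(q$exons[[1]])
  if (nrow(im) == 0) return(im)
  if (q$strand == "+") {
    im <- im[im[, 1] >= r$stop_end, , drop = FALSE]
    im[order(im[, 1]), , drop = FALSE]
  } else {
    im <- im[im[, 2] <= r$stop_start, , drop = FALSE]
    im[order(-im[, 2]), , drop = FALSE]
  }
}

# Spliced distance from the base immediately after the reference stop codon to
# the intron donor, along the query's exons.
distance_to_stop_rows <- function(q, r, intron) {
  exons <- q$exons[[1]]
  if (q$strand == "+") {
    exonic_bases_between(exons, r$stop_end, intron[1])
  } else {
    exonic_bases_between(exons, intron[2], r$stop_start)
  }
}

#' Spliced distance from a reference stop codon to a 3UI donor
#'
#' @inheritParams cds_chain_match
#' @param intron Integer vector `c(start, end)` of the intron (0-based
#'   half-open); must be an intron of the query downstream of the reference
#'   stop codon.
#' @return Non-negative integer distance in exonic nucleotides.
#' @export
distance_to_stop <- function(models, transcript_id, refs, ref_id, intron) {
  q <- model_row(models, transcript_id)
  r <- model_row(refs, ref_id)
  distance_to_stop_rows(q, r, intron)
}

#' Detect and classify 3' UTR introns
#'
#' The core classifier. Each query transcript is compared against every
#' high-confidence reference whose start codon falls in a query exon; where
#' the query reproduces the reference's intron chain across the CDS span, all
#' query introns downstream of the reference stop codon are reported as 3UIs.
#' An intron sharing its donor or acceptor position with any coding intron in
#' the full reference annotation is classed `co3UI`, otherwise `e3UI`; an
#' intron whose exact junction appears in no reference transcript is flagged
#' `novel`. The spliced distance from the stop codon to the intron donor is
#' recorded per matched reference, and the record carrying each transcript's
#' maximal distance is flagged (ties broken towards the transcript-3' intron).
#'
#' @param queries Query transcript model tibble (assembly).
#' @param refs_hc High-confidence reference model tibble (matching targets).
#' @param indices `reference_indices` built from the full annotation.
#' @return A tibble with one row per (intron, matched reference) pair:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `intron_start`,
#'   `intron_end`, `matched_reference_id`, `klass` (`e3UI`/`co3UI`), `novel`,
#'   `distance_to_stop`, `genomic_distance_to_stop`, `max_distance_flag`.
#'   Unclassified transcripts are listed in the `"skipped"` attribute with a
#'   reason.
#' @export
classify_utr_introns <- function(queries, refs_hc, indices) {
  stopifnot(inherits(indices, "reference_indices"))
  cb <- indices$coding_boundaries
  coding_keys <- boundary_keys(cb$chrom, cb$strand, cb$pos, cb$side)
  aj <- indices$all_junctions
  junc_keys <- junction_keys(aj$chrom, aj$strand, aj$start, aj$end)

  skipped <- list()
  recs <- list()
  for (i in order(queries$transcript_id)) {
    q <- queries[i, ]
    cand <- candidate_refs_row(q, refs_hc)
    if (nrow(cand) == 0) {
      skipped[[length(skipped) + 1]] <-
        tibble(transcript_id = q$transcript_id,
               reason = "no_candidate_reference")
      next
    }
    matched <- cand[vapply(seq_len(nrow(cand)), function(j) {
      cds_chain_match_rows(q, cand[j, ])
    }, logical(1)), , drop = FALSE]
    if (nrow(matched) == 0) {
      skipped[[length(skipped) + 1]] <-
        tibble(transcript_id = q$transcript_id,
               reason = "no_cds_chain_match")
      next
    }
    any_record <- FALSE
    for (j in order(matched$transcript_id)) {
      r <- matched[j, ]
      uim <- utr_introns_rows(q, r)
      if (nrow(uim) == 0) next
      any_record <- TRUE
      donor <- if (q$strand == "+") uim[, 1] else uim[, 2]
      acceptor <- if (q$strand == "+") uim[, 2] else uim[, 1]
      is_co <- boundary_keys(q$chrom, q$strand, donor, "donor") %in%
        coding_keys |
        boundary_keys(q$chrom, q$strand, acceptor, "acceptor") %in% coding_keys
      novel <- !(junction_keys(q$chrom, q$strand, uim[, 1], uim[, 2]) %in%
                   junc_keys)
      dist <- vapply(seq_len(nrow(uim)), function(k) {
        distance_to_stop_rows(q, r, uim[k, ])
      }, integer(1))
      gdist <- if (q$strand == "+") uim[, 1] - r$stop_end else
        r$stop_start - uim[, 2]
      recs[[length(recs) + 1]] <- tibble(
        transcript_id = q$transcript_id,
        gene_id = q$gene_id,
        chrom = q$chrom,
        strand = q$strand,
        intron_start = as.integer(uim[, 1]),
        intron_end = as.integer(uim[, 2]),
        matched_reference_id = r$transcript_id,
        klass = ifelse(is_co, "co3UI", "e3UI"),
        novel = novel,
        distance_to_stop = dist,
        genomic_distance_to_stop = as.integer(gdist)
      )
    }
    if (!any_record) {
      skipped[[length(skipped) + 1]] <-
        tibble(transcript_id = q$transcript_id, reason = "no_utr_introns")
    }
  }
  out <- bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble(transcript_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  intron_start = integer(0), intron_end = integer(0),
                  matched_reference_id = character(0), klass = character(0),
                  novel = logical(0), distance_to_stop = integer(0),
                  genomic_distance_to_stop = integer(0))
  }
  out$max_distance_flag <- flag_max_distance(out)
  skipped_tbl <- bind_rows(skipped)
  if (nrow(skipped_tbl) == 0) {
    skipped_tbl <- tibble(transcript_id = character(0), reason = character(0))
  }
  attr(out, "skipped") <- skipped_tbl
  out
}

# One flag per transcript, on the record with the maximal spliced distance;
# ties go to the most transcript-3' intron (largest transcript-coordinate
# donor), then to the lexicographically first reference id.
flag_max_distance <- function(records) {
  if (nrow(records) == 0) return(logical(0))
  donor_rank <- ifelse(records$strand == "+", records$intron_start,
                       -records$intron_end)
  flag <- logical(nrow(records))
  for (tx in unique(records$transcript_id)) {
    idx <- which(records$transcript_id == tx)
    ord <- idx[order(-records$distance_to_stop[idx], -donor_rank[idx],
                     records$matched_reference_id[idx])]
    flag[ord[1]] <- TRUE
  }
  flag
}

#' Maximal stop-codon distance of a transcript's 3UIs
#'
#' @param records Record tibble for a single transcript (at least one row).
#' @return Integer: the maximum `distance_to_stop` across records.
#' @export
max_distance <- function(records) {
  if (nrow(records) == 0) {
    abort("no records: max_distance needs at least one 3UI record",
          class = "utrintrons_validation_error")
  }
  max(records$distance_to_stop)
}

#' Expected NMD sensitivity under the 55-nt rule
#'
#' A splice junction more than `threshold` exonic nucleotides downstream of
#' the stop codon is classically expected to sensitize the transcript to
#' nonsense-mediated decay. The comparison is strict, so a distance exactly at
#' the threshold is not expected to be sensitizing.
#'
#' @param distance Numeric vector of non-negative spliced distances (nt).
#' @param threshold Rule threshold in nucleotides (default 55; 50 is the other
#'   commonly quoted value).
#' @return A tibble `distance`, `threshold_nt`, `expected_sensitive`.
#' @export
nmd_expectation <- function(distance, threshold = 55) {
  if (any(distance < 0)) {
    abort("distances must be non-negative",
          class = "utrintrons_validation_error")
  }
  tibble(distance = distance, threshold_nt = threshold,
         expected_sensitive = distance > threshold)
}

#' Export 3UI-containing transcripts with the implied CDS
#'
#' Writes a GTF of the query transcripts that produced records, copying the
#' CDS span and stop codon from each transcript's matched reference (the
#' flagged record's reference when a transcript matched several).
#'
#' @param records Record tibble from [classify_utr_introns()].
#' @param queries Query model tibble.
#' @param refs Reference model tibble.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_implied_cds_gtf <- function(records, queries, refs, path) {
  picks <- records[records$max_distance_flag, , drop = FALSE]
  out <- queries[match(picks$transcript_id, queries$transcript_id), ,
                 drop = FALSE]
  ref_rows <- refs[match(picks$matched_reference_id, refs$transcript_id), ,
                   drop = FALSE]
  out$cds <- ref_rows$cds
  out$cds_start <- ref_rows$cds_start
  out$cds_end <- ref_rows$cds_end
  out$stop_start <- ref_rows$stop_start
  out$stop_end <- ref_rows$stop_end
  out$stop_split <- ref_rows$stop_split
  write_gtf(out, path)
}
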