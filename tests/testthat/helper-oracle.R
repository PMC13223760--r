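# Literal brute-force 3UI classifier used as an independent oracle. Works by
# enumerating every exonic base of a transcript in transcript order, so all
# strand handling, distances and "between start and stop" tests are derived
# from explicit base indices rather than interval arithmetic.

oracle_positions <- function(row) {
  ex <- row$exons[[1]]
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq.int(ex[i, 1], ex[i, 2] - 1L)
  }))
  if (row$strand == "-") pos <- rev(pos)
  pos
}

oracle_introns <- function(row) {
  # introns as (start, end, donor_pos, acceptor_pos) via transcript-order gaps
  pos <- oracle_positions(row)
  out <- list()
  if (length(pos) >= 2) {
    for (k in seq_len(length(pos) - 1)) {
      g1 <- pos[k]
      g2 <- pos[k + 1]
      if (abs(g2 - g1) > 1) {
        if (row$strand == "+") {
          out[[length(out) + 1]] <- c(start = g1 + 1L, end = g2,
                                      donor = g1 + 1L, acceptor = g2,
                                      before_idx = k)
        } else {
          out[[length(out) + 1]] <- c(start = g2 + 1L, end = g1,
                                      donor = g1, acceptor = g2 + 1L,
                                      before_idx = k)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(matrix(integer(0), ncol = 5,
                  dimnames = list(NULL, c("start", "end", "donor", "acceptor",
                                          "before_idx"))))
  }
  do.call(rbind, out)
}

oracle_coding_boundaries <- function(refs_full) {
  keys <- character(0)
  for (i in seq_len(nrow(refs_full))) {
    r <- refs_full[i, ]
    if (is.na(r$cds_start) || is.na(r$stop_start)) next
    pos <- oracle_positions(r)
    start_base <- if (r$strand == "+") r$cds_start else r$cds_end - 1L
    stop_last <- if (r$strand == "+") r$stop_end - 1L else r$stop_start
    i_start <- match(start_base, pos)
    i_stop <- match(stop_last, pos)
    if (is.na(i_start) || is.na(i_stop)) next
    im <- oracle_introns(r)
    for (k in seq_len(nrow(im))) {
      if (im[k, "before_idx"] >= i_start && im[k, "before_idx"] + 1 <= i_stop) {
        keys <- c(keys,
                  paste(r$chrom, r$strand, im[k, "donor"], "donor"),
                  paste(r$chrom, r$strand, im[k, "acceptor"], "acceptor"))
      }
    }
  }
  unique(keys)
}

oracle_all_junctions <- function(refs_full) {
  keys <- character(0)
  for (i in seq_len(nrow(refs_full))) {
    r <- refs_full[i, ]
    im <- oracle_introns(r)
    if (nrow(im) > 0) {
      keys <- c(keys, paste(r$chrom, r$strand, im[, "start"], im[, "end"]))
    }
  }
  unique(keys)
}

oracle_classify <- function(queries, refs_hc, refs_full) {
  coding <- oracle_coding_boundaries(refs_full)
  junctions <- oracle_all_junctions(refs_full)
  rows <- list()
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    qpos <- oracle_positions(q)
    qim <- oracle_introns(q)
    for (j in seq_len(nrow(refs_hc))) {
      r <- refs_hc[j, ]
      if (r$chrom != q$chrom || r$strand != q$strand) next
      if (is.na(r$cds_start) || is.na(r$stop_start)) next
      start_base <- if (r$strand == "+") r$cds_start else r$cds_end - 1L
      qe <- q$exons[[1]]
      if (!any(qe[, 1] <= start_base & start_base < qe[, 2])) next
      in_span <- function(m) {
        if (nrow(m) == 0) return(character(0))
        sel <- m[, "start"] >= r$cds_start & m[, "end"] <= r$cds_end
        sort(paste(m[sel, "start"], m[sel, "end"]))
      }
      if (!identical(in_span(qim), in_span(oracle_introns(r)))) next
      stop_last <- if (r$strand == "+") r$stop_end - 1L else r$stop_start
      i_stop <- match(stop_last, qpos)
      if (is.na(i_stop)) next
      for (k in seq_len(nrow(qim))) {
        b <- qim[k, "before_idx"]
        if (b < i_stop) next
        is_co <- paste(q$chrom, q$strand, qim[k, "donor"], "donor") %in%
          coding ||
          paste(q$chrom, q$strand, qim[k, "acceptor"], "acceptor") %in% coding
        rows[[length(rows) + 1]] <- tibble::tibble(
          transcript_id = q$transcript_id,
          matched_reference_id = r$transcript_id,
          intron_start = as.integer(qim[k, "start"]),
          intron_end = as.integer(qim[k, "end"]),
          klass = if (is_co) "co3UI" else "e3UI",
          novel = !(paste(q$chrom, q$strand, qim[k, "start"],
                          qim[k, "end"]) %in% junctions),
          distance_to_stop = as.integer(b - i_stop))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(transcript_id = character(0),
                          matched_reference_id = character(0),
                          intron_start = integer(0), intron_end = integer(0),
                          klass = character(0), novel = logical(0),
                          distance_to_stop = integer(0))
  }
  out
}

# Random small locus: <= 3 references, <= 4 introns per transcript, with
# mutations exercising chain mismatches, extra stops and novel donors.
random_instance <- function(seed) {
  set.seed(seed)
  strand <- sample(c("+", "-"), 1)
  utr5 <- sample(20:80, 1)
  n_cds <- sample(0:2, 1)
  chunk <- sample(40:90, 1)
  cds_intron <- sample(60:150, 1)
  d <- sample(0:120, 1)
  L <- sample(60:200, 1)
  cds_start <- utr5
  cds_end <- utr5 + (n_cds + 1) * chunk + n_cds * cds_intron
  stop_end <- cds_end + 3L
  ui <- c(stop_end + d, stop_end + d + L)
  span <- ui[2] + 100L
  cds_introns <- if (n_cds > 0) {
    t(vapply(seq_len(n_cds), function(i) {
      c(cds_start + i * chunk + (i - 1) * cds_intron,
        cds_start + i * (chunk + cds_intron))
    }, numeric(2)))
  } else matrix(integer(0), ncol = 2)
  cds_chunks <- cbind(c(cds_start, if (n_cds > 0) cds_introns[, 2]),
                      c(if (n_cds > 0) cds_introns[, 1], cds_end))
  mirror <- function(m) {
    if (nrow(m) == 0) return(m)
    r <- cbind(span - m[, 2], span - m[, 1])
    r[order(r[, 1]), , drop = FALSE]
  }
  pl <- function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    if (strand == "-") mirror(m) else m
  }
  complement <- function(introns) {
    if (nrow(introns) == 0) return(cbind(0L, span))
    introns <- introns[order(introns[, 1]), , drop = FALSE]
    cbind(c(0L, introns[, 2]), c(introns[, 1], span))
  }
  iv <- function(a, b) rbind(c(a, b))

  stop_iv <- pl(iv(cds_end, stop_end))[1, ]
  refs <- list(utrintrons:::new_model_row(
    "RA", "G", "chr1", strand, pl(complement(cds_introns)),
    cds = pl(cds_chunks), stop = stop_iv, tsl = "1",
    appris = "appris_principal_1"))
  if (runif(1) < 0.5) {
    hc <- runif(1) < 0.5
    refs[[length(refs) + 1]] <- utrintrons:::new_model_row(
      "RB", "G", "chr1", strand, pl(complement(rbind(cds_introns, ui))),
      cds = pl(cds_chunks), stop = stop_iv,
      tsl = if (hc) "1" else "5",
      appris = if (hc) "appris_principal_1" else NA_character_)
  }
  if (runif(1) < 0.4) {
    early_end <- cds_start + sample(10:(chunk - 10), 1)
    refs[[length(refs) + 1]] <- utrintrons:::new_model_row(
      "RD", "G", "chr1", strand, pl(complement(cds_introns)),
      cds = pl(iv(cds_start, early_end)),
      stop = pl(iv(early_end, early_end + 3L))[1, ],
      tsl = "2", appris = "appris_alternative_1")
  }
  refs <- dplyr::bind_rows(refs)

  mode <- sample(c("spliced", "retained", "dropped", "shifted"), 1)
  q_introns <- switch(mode,
    spliced = rbind(cds_introns, ui),
    retained = cds_introns,
    dropped = if (n_cds > 0) rbind(cds_introns[-1, , drop = FALSE], ui) else
      rbind(cds_introns, ui),
    shifted = rbind(cds_introns, ui + c(3L, 0L)))
  query <- utrintrons:::new_model_row("Q", "G", "chr1", strand,
                                      pl(complement(q_introns)))
  list(query = query, refs = refs,
       refs_hc = filter_high_confidence(refs))
}
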