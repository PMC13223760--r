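# Hand-built transcript models for unit tests, bypassing GTF files.

mk_tx <- function(id, exons, gene = paste0(id, "_g"), chrom = "chr1",
                  strand = "+", cds = NULL, stop = NULL, tsl = NA_character_,
                  appris = NA_character_, biotype = NA_character_) {
  ex <- do.call(rbind, exons)
  storage.mode(ex) <- "integer"
  cds_m <- if (is.null(cds)) NULL else {
    m <- do.call(rbind, cds)
    storage.mode(m) <- "integer"
    m
  }
  utrintrons:::new_model_row(id, gene, chrom, strand, ex, cds = cds_m,
                             stop = stop, tsl = tsl, appris = appris,
                             biotype = biotype)
}

mk_models <- function(...) dplyr::bind_rows(...)

# Reflect all models through x -> L - x and flip strand; preserves intron
# lengths, spliced distances, classes and novelty.
reflect_models <- function(models, L) {
  out <- lapply(seq_len(nrow(models)), function(i) {
    row <- models[i, ]
    flip_iv <- function(m) {
      if (is.null(m) || nrow(m) == 0) return(m)
      r <- cbind(L - m[, 2], L - m[, 1])
      storage.mode(r) <- "integer"
      r[order(r[, 1]), , drop = FALSE]
    }
    exons <- flip_iv(row$exons[[1]])
    cds <- flip_iv(row$cds[[1]])
    stop <- if (is.na(row$stop_start)) NULL else
      c(L - row$stop_end, L - row$stop_start)
    utrintrons:::new_model_row(
      row$transcript_id, row$gene_id, row$chrom,
      if (row$strand == "+") "-" else "+", exons, cds = cds, stop = stop,
      tsl = row$tsl, appris = row$appris, biotype = row$biotype)
  })
  dplyr::bind_rows(out)
}

reflect_genome <- function(genome) {
  Biostrings::reverseComplement(genome)
}

# Sorted, comparable view of a record table for equality assertions.
record_key <- function(records) {
  df <- as.data.frame(records[, c("transcript_id", "matched_reference_id",
                                  "intron_start", "intron_end", "klass",
                                  "novel", "distance_to_stop")])
  df <- df[do.call(order, df), , drop = FALSE]
  attributes(df) <- attributes(df)[c("names", "class")]
  rownames(df) <- NULL
  df
}

# Records of a reflected locus mapped back to original coordinates.
unreflect_records <- function(records, L) {
  out <- records
  out$intron_start <- as.integer(L - records$intron_end)
  out$intron_end <- as.integer(L - records$intron_start)
  out$strand <- ifelse(records$strand == "+", "-", "+")
  out
}
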