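#' Read a genome FASTA into a named sequence set
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first word of each
#'   header.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- stringr::word(names(genome), 1)
  genome
}

#' Extract the sense-strand sequence of a genomic interval
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus-strand intervals are
#'   reverse-complemented so the result reads 5' to 3' on the transcript.
#' @return Uppercase character scalar.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome not in genome: ", chrom),
          class = "utrintrons_lookup_error")
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    abort(paste0("interval [", start, ",", end, ") out of bounds for ",
                 chrom, " (length ", len, ")"),
          class = "utrintrons_coordinate_error")
  }
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

#' GC fraction of a sequence
#'
#' Ambiguity codes are excluded from both numerator and denominator, so only
#' unambiguous A/C/G/T bases count.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) {
    abort("gc_content of an empty sequence is undefined",
          class = "utrintrons_validation_error")
  }
  vapply(toupper(seq), function(s) {
    counts <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                          c("A", "C", "G", "T"))
    total <- sum(counts)
    if (total == 0) return(NA_real_)
    unname((counts[["C"]] + counts[["G"]]) / total)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Splice-site dinucleotides of introns
#'
#' Reports the first and last two sense-strand bases of each intron and
#' whether the pair is the canonical GT-AG. GC-AG and AT-AC minor sites are
#' reported but counted non-canonical.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param introns Tibble with columns `chrom`, `strand`, `intron_start`,
#'   `intron_end` (0-based half-open).
#' @return The input with `donor2`, `acceptor2` and `canonical` columns added.
#' @export
splice_dinucleotides <- function(genome, introns) {
  if (any(introns$intron_end - introns$intron_start < 4)) {
    abort("introns shorter than 4 nt have no distinct splice dinucleotides",
          class = "utrintrons_validation_error")
  }
  seqs <- vapply(seq_len(nrow(introns)), function(i) {
    extract_sequence(genome, introns$chrom[i], introns$intron_start[i],
                     introns$intron_end[i], introns$strand[i])
  }, character(1))
  introns$donor2 <- substr(seqs, 1, 2)
  introns$acceptor2 <- substr(seqs, nchar(seqs) - 1, nchar(seqs))
  introns$canonical <- introns$donor2 == "GT" & introns$acceptor2 == "AG"
  introns
}

#' Count DRACH motif occurrences
#'
#' Counts every position matching the m6A consensus D=\[AGT\], R=\[AG\], A, C,
#' H=\[ACT\] on the given (sense) sequence; overlapping matches all count.
#' U is treated as T.
#'
#' @param seq Character vector of DNA/RNA sequences.
#' @return Integer vector of counts (0 for sequences shorter than 5).
#' @export
drach_count <- function(seq) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  vapply(seq, function(s) {
    if (nchar(s) < 5) return(0L)
    Biostrings::countPattern("DRACH", Biostrings::DNAString(s),
                             fixed = FALSE)
  }, integer(1), USE.NAMES = FALSE)
}

#' Append sequence features to a 3UI record table
#'
#' Adds intron length, GC fraction, splice-site dinucleotides with the
#' canonical GT-AG flag, and the DRACH motif count of each intron.
#'
#' @param records Record tibble from [classify_utr_introns()].
#' @param genome A [Biostrings::DNAStringSet].
#' @return `records` with `length_nt`, `gc_fraction`, `donor2`, `acceptor2`,
#'   `canonical` and `drach_count` columns added.
#' @export
add_intron_features <- function(records, genome) {
  records$length_nt <- records$intron_end - records$intron_start
  if (nrow(records) == 0) {
    records$gc_fraction <- numeric(0)
    records$donor2 <- character(0)
    records$acceptor2 <- character(0)
    records$canonical <- logical(0)
    records$drach_count <- integer(0)
    return(records)
  }
  seqs <- vapply(seq_len(nrow(records)), function(i) {
    extract_sequence(genome, records$chrom[i], records$intron_start[i],
                     records$intron_end[i], records$strand[i])
  }, character(1))
  records$gc_fraction <- gc_content(seqs)
  records$donor2 <- substr(seqs, 1, 2)
  records$acceptor2 <- substr(seqs, nchar(seqs) - 1, nchar(seqs))
  records$canonical <- records$donor2 == "GT" & records$acceptor2 == "AG"
  records$drach_count <- drach_count(seqs)
  records
}
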