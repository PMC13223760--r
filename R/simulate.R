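#' Plan a synthetic 3UI fixture
#'
#' Builds a deterministic, seeded plan for a synthetic locus set: per gene a
#' 3UI class (`none`, `e3UI`, `co3UI`, `novel_e3UI`), a number of CDS introns,
#' a planted UTR intron length and stop-codon distance, and a strand; plus a
#' sample plan (normal/cancer), expression and PSO plans, and a regulator
#' plan with target Spearman correlations per condition. The seed fully
#' determines the plan and every downstream draw.
#'
#' @param n_genes Number of genes (default 50).
#' @param seed Integer seed.
#' @param n_normal,n_cancer Samples per condition (default 25 each).
#' @param gc Background genome GC fraction (default 0.42).
#' @param min_intron_length Floor for planted UTR intron lengths (default 60).
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters for planted
#'   transcripts.
#' @param pso_plan Named list of per-class PSO Beta means per condition and a
#'   common concentration.
#' @param regulator Target Spearman correlations between the regulator gene's
#'   expression and mean e3UI PSO, per condition.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 50, seed = 1, n_normal = 25, n_cancer = 25,
                         gc = 0.42, min_intron_length = 60,
                         tpm_meanlog = log(20), tpm_sdlog = 0.8,
                         pso_plan = list(
                           e3UI = c(normal = 0.40, cancer = 0.50),
                           co3UI = c(normal = 0.45, cancer = 0.40),
                           concentration = 20),
                         regulator = list(rho_normal = -0.34,
                                          rho_cancer = 0.11)) {
  stopifnot(n_genes >= 1, n_normal >= 1, n_cancer >= 1, gc > 0, gc < 1,
            min_intron_length >= 4)
  for (r in c(regulator$rho_normal, regulator$rho_cancer)) {
    if (abs(r) >= 1) {
      abort("target correlations must lie in (-1, 1)",
            class = "utrintrons_validation_error")
    }
  }
  plan <- with_preserved_seed(seed, {
    classes <- sample(c("e3UI", "co3UI", "novel_e3UI", "none"), n_genes,
                      replace = TRUE, prob = c(0.30, 0.25, 0.25, 0.20))
    tibble(
      gene_id = sprintf("GENE%03d", seq_len(n_genes)),
      class = classes,
      n_cds_introns = sample(0:3, n_genes, replace = TRUE),
      utr_intron_length = sample(seq(min_intron_length, 400), n_genes,
                                 replace = TRUE),
      distance_to_stop = sample(c(8L, 15L, 35L, 55L, 56L, 80L, 135L, 200L,
                                  300L), n_genes, replace = TRUE),
      strand = rep_len(c("+", "-"), n_genes),
      decoy_fragment = seq_len(n_genes) %% 5 == 0,
      decoy_antisense = seq_len(n_genes) %% 6 == 0,
      decoy_intronic = FALSE
    )
  })
  plan$decoy_intronic <- seq_len(n_genes) %% 7 == 0 & plan$n_cds_introns >= 1
  structure(
    list(seed = as.integer(seed), n_genes = n_genes, gene_plan = plan,
         n_normal = n_normal, n_cancer = n_cancer, gc = gc,
         tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
         pso_plan = pso_plan, regulator = regulator),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture_spec> seed", x$seed, "-", x$n_genes, "genes,",
      x$n_normal, "normal +", x$n_cancer, "cancer samples\n")
  print(table(x$gene_plan$class))
  invisible(x)
}

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Local (gene-relative) layout, transcript order. All lengths in nt.
gene_layout <- function(n_cds_introns, d, L) {
  utr5 <- 100L
  chunk <- 60L
  cds_intron <- 90L
  n <- n_cds_introns
  cds_start <- utr5
  cds_end <- utr5 + (n + 1L) * chunk + n * cds_intron
  stop_start <- cds_end
  stop_end <- cds_end + 3L
  ui_start <- stop_end + d
  ui_end <- ui_start + L
  span <- ui_end + 120L
  cds_introns <- if (n > 0) {
    cbind(cds_start + seq_len(n) * chunk + (seq_len(n) - 1L) * cds_intron,
          cds_start + seq_len(n) * (chunk + cds_intron))
  } else matrix(integer(0), ncol = 2)
  cds_chunks <- cbind(
    c(cds_start, if (n > 0) cds_introns[, 2]),
    c(if (n > 0) cds_introns[, 1], cds_end)
  )
  list(span = span, cds_start = cds_start, cds_end = cds_end,
       stop_start = stop_start, stop_end = stop_end,
       ui_start = ui_start, ui_end = ui_end,
       cds_introns = cds_introns, cds_chunks = cds_chunks)
}

# Complement of sorted introns within [0, span).
local_exons <- function(introns, span) {
  if (nrow(introns) == 0) return(cbind(0L, span))
  introns <- introns[order(introns[, 1]), , drop = FALSE]
  starts <- c(0L, introns[, 2])
  ends <- c(introns[, 1], span)
  cbind(starts, ends)
}

# Map a local interval matrix to genomic coordinates; minus-strand genes are
# mirrored within the gene span so transcript order is preserved.
place <- function(m, offset, span, strand) {
  if (nrow(m) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  out <- if (strand == "+") {
    cbind(offset + m[, 1], offset + m[, 2])
  } else {
    cbind(offset + span - m[, 2], offset + span - m[, 1])
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

new_model_row <- function(transcript_id, gene_id, chrom, strand, exons,
                          cds = NULL, stop = NULL, tsl = NA_character_,
                          appris = NA_character_, biotype = NA_character_) {
  n_ex <- nrow(exons)
  tx_start <- as.integer(exons[1, 1])
  tx_end <- as.integer(exons[n_ex, 2])
  cds_start <- if (is.null(cds)) NA_integer_ else as.integer(min(cds[, 1]))
  cds_end <- if (is.null(cds)) NA_integer_ else as.integer(max(cds[, 2]))
  stop_start <- if (is.null(stop)) NA_integer_ else as.integer(stop[1])
  stop_end <- if (is.null(stop)) NA_integer_ else as.integer(stop[2])
  tibble(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = list(exons), cds = list(cds),
    n_exons = n_ex, tx_start = tx_start, tx_end = tx_end,
    cds_start = cds_start, cds_end = cds_end,
    stop_start = stop_start, stop_end = stop_end, stop_split = FALSE,
    tsl = tsl, appris = appris, biotype = biotype
  )
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Materializes a [fixture_spec()] into a genome (random sequence with
#' GT..AG planted at every intron boundary and TAA at stop codons), a
#' reference annotation (with CDS, stop codons and TSL/APPRIS attributes), a
#' query assembly (exon features only, including fragment / intron-contained
#' / antisense decoys), TPM, junction-count and PSI tables, and a truth table
#' recording each planted 3UI's class, novelty and stop distance. The same
#' seed always yields byte-identical outputs.
#'
#' @param spec A `fixture_spec`.
#' @param outdir Optional directory; when given, all components are written
#'   as plain-text files (FASTA/GTF/TSV) plus a manifest.
#' @return An object of class `utr_fixture`: a list with `genome`,
#'   `reference`, `assembly`, `truth`, `decoys`, `tpm`, `tx2gene`,
#'   `junction_counts`, `psi`, `event_classes`, `sample_sheet`, `spec` and
#'   (when written) `paths`.
#' @export
make_fixture <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  plan <- spec$gene_plan
  if (any(plan$utr_intron_length < 4) || any(plan$distance_to_stop < 0) ||
      any(plan$n_cds_introns < 0)) {
    abort("unrealizable gene plan: intron lengths must be >= 4 and distances >= 0",
          class = "utrintrons_validation_error")
  }
  chrom <- "chrF"
  gap <- 500L
  ref_rows <- list()
  asm_rows <- list()
  truth_rows <- list()
  decoy_rows <- list()
  planted_stops <- list()
  planted_starts <- list()
  offset <- gap

  for (g in seq_len(nrow(plan))) {
    p <- plan[g, ]
    lay <- gene_layout(p$n_cds_introns, p$distance_to_stop,
                       p$utr_intron_length)
    S <- lay$span
    strand <- p$strand
    gid <- p$gene_id
    pl <- function(m) place(m, offset, S, strand)

    ref_a_exons <- pl(local_exons(lay$cds_introns, S))
    cds_chunks <- pl(lay$cds_chunks)
    stop_iv <- pl(rbind(c(lay$stop_start, lay$stop_end)))
    ui <- rbind(c(lay$ui_start, lay$ui_end))
    spliced_introns <- rbind(lay$cds_introns, ui)
    query_exons <- pl(local_exons(spliced_introns, S))

    ref_rows[[length(ref_rows) + 1]] <- new_model_row(
      paste0("REF_", gid, "_A"), gid, chrom, strand, ref_a_exons,
      cds = cds_chunks, stop = c(stop_iv[1, 1], stop_iv[1, 2]),
      tsl = "1", appris = "appris_principal_1", biotype = "protein_coding")
    planted_stops[[length(planted_stops) + 1]] <-
      c(stop_iv[1, 1], stop_iv[1, 2], strand)
    planted_starts[[length(planted_starts) + 1]] <-
      c(pl(rbind(c(lay$cds_start, lay$cds_start + 3L)))[1, ], strand)

    qid <- paste0("TX_", gid)
    if (p$class == "none") {
      asm_rows[[length(asm_rows) + 1]] <- new_model_row(
        qid, gid, chrom, strand, ref_a_exons)
    } else {
      asm_rows[[length(asm_rows) + 1]] <- new_model_row(
        qid, gid, chrom, strand, query_exons)
      ui_g <- pl(ui)
      klass <- if (p$class == "co3UI") "co3UI" else "e3UI"
      novel <- p$class == "novel_e3UI"
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        transcript_id = qid, gene_id = gid, chrom = chrom, strand = strand,
        intron_start = as.integer(ui_g[1, 1]),
        intron_end = as.integer(ui_g[1, 2]),
        klass = klass, novel = novel,
        distance = as.integer(p$distance_to_stop))

      if (p$class == "e3UI") {
        # annotated companion isoform carrying the same post-stop intron;
        # low TSL keeps it out of the matching target set
        ref_rows[[length(ref_rows) + 1]] <- new_model_row(
          paste0("REF_", gid, "_B"), gid, chrom, strand, query_exons,
          cds = cds_chunks, stop = c(stop_iv[1, 1], stop_iv[1, 2]),
          tsl = "5", biotype = "protein_coding")
      } else if (p$class == "co3UI") {
        # isoform with a later stop codon: the planted intron sits inside its
        # CDS, making its boundaries coding boundaries
        cds_c_local <- rbind(
          lay$cds_chunks,
          c(lay$cds_end, lay$ui_start),
          c(lay$ui_end, lay$ui_end + 30L))
        stop_c <- pl(rbind(c(lay$ui_end + 30L, lay$ui_end + 33L)))
        ref_rows[[length(ref_rows) + 1]] <- new_model_row(
          paste0("REF_", gid, "_C"), gid, chrom, strand, query_exons,
          cds = pl(cds_c_local), stop = c(stop_c[1, 1], stop_c[1, 2]),
          tsl = "NA", biotype = "protein_coding")
        planted_stops[[length(planted_stops) + 1]] <-
          c(stop_c[1, 1], stop_c[1, 2], strand)
      }
    }

    if (p$decoy_fragment) {
      did <- paste0("DECOY_", gid, "_frag")
      fe <- if (nrow(ref_a_exons) >= 2) {
        rbind(c(ref_a_exons[1, 1] + 15L, ref_a_exons[1, 2]),
              c(ref_a_exons[2, 1], ref_a_exons[2, 1] + 30L))
      } else {
        rbind(c(ref_a_exons[1, 1] + 10L, ref_a_exons[1, 1] + 90L))
      }
      asm_rows[[length(asm_rows) + 1]] <- new_model_row(
        did, gid, chrom, strand, fe)
      decoy_rows[[length(decoy_rows) + 1]] <-
        tibble(transcript_id = did, decoy_type = "fragment")
    }
    if (p$decoy_intronic) {
      first_intron <- pl(lay$cds_introns)[1, , drop = FALSE]
      did <- paste0("DECOY_", gid, "_intr")
      asm_rows[[length(asm_rows) + 1]] <- new_model_row(
        did, gid, chrom, strand,
        rbind(c(first_intron[1, 1] + 10L, first_intron[1, 1] + 70L)))
      decoy_rows[[length(decoy_rows) + 1]] <-
        tibble(transcript_id = did, decoy_type = "contained_intronic")
    }
    if (p$decoy_antisense) {
      did <- paste0("DECOY_", gid, "_anti")
      anti_strand <- if (strand == "+") "-" else "+"
      asm_rows[[length(asm_rows) + 1]] <- new_model_row(
        did, gid, chrom, anti_strand,
        rbind(c(ref_a_exons[1, 1] + 20L, ref_a_exons[1, 1] + 200L)))
      decoy_rows[[length(decoy_rows) + 1]] <-
        tibble(transcript_id = did, decoy_type = "antisense")
    }
    offset <- offset + S + gap
  }

  genome_len <- offset
  reference <- bind_rows(ref_rows)
  assembly <- bind_rows(asm_rows)
  truth <- bind_rows(truth_rows)
  if (nrow(truth) == 0) {
    truth <- tibble(transcript_id = character(0), gene_id = character(0),
                    chrom = character(0), strand = character(0),
                    intron_start = integer(0), intron_end = integer(0),
                    klass = character(0), novel = logical(0),
                    distance = integer(0))
  }
  decoys <- bind_rows(decoy_rows)
  if (nrow(decoys) == 0) {
    decoys <- tibble(transcript_id = character(0), decoy_type = character(0))
  }

  samples <- c(sprintf("normal_%02d", seq_len(spec$n_normal)),
               sprintf("cancer_%02d", seq_len(spec$n_cancer)))
  sample_sheet <- tibble(
    sample = samples,
    condition = rep(c("normal", "cancer"), c(spec$n_normal, spec$n_cancer)))

  out <- with_preserved_seed(spec$seed + 1L, {
    base <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE,
                   prob = c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2,
                            (1 - spec$gc) / 2))
    all_introns <- transcript_introns(bind_rows(reference, assembly))
    all_introns <- distinct(all_introns[, c("strand", "intron_start",
                                            "intron_end")])
    for (i in seq_len(nrow(all_introns))) {
      s <- all_introns$intron_start[i]
      e <- all_introns$intron_end[i]
      if (all_introns$strand[i] == "+") {
        base[s + 1:2] <- c("G", "T")
        base[(e - 1):e] <- c("A", "G")
      } else {
        base[(e - 1):e] <- c("A", "C")
        base[s + 1:2] <- c("C", "T")
      }
    }
    for (st in planted_stops) {
      s <- as.integer(st[1])
      cod <- if (st[3] == "+") c("T", "A", "A") else c("T", "T", "A")
      base[s + 1:3] <- cod
    }
    for (st in planted_starts) {
      s <- as.integer(st[1])
      cod <- if (st[3] == "+") c("A", "T", "G") else c("C", "A", "T")
      base[s + 1:3] <- cod
    }
    genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
    names(genome) <- chrom

    n_tx <- nrow(assembly)
    is_decoy <- assembly$transcript_id %in% decoys$transcript_id
    meanlog <- ifelse(is_decoy, log(5), spec$tpm_meanlog)
    sdlog <- ifelse(is_decoy, 0.5, spec$tpm_sdlog)
    tpm_mat <- matrix(stats::rlnorm(n_tx * length(samples),
                                    meanlog = rep(meanlog, length(samples)),
                                    sdlog = rep(sdlog, length(samples))),
                      nrow = n_tx)
    tpm <- as_tibble(as.data.frame(round(tpm_mat, 4)))
    names(tpm) <- samples
    tpm <- dplyr::bind_cols(tibble(transcript_id = assembly$transcript_id),
                            tpm)

    jx <- distinct(transcript_junctions(assembly)[, c("chrom", "strand",
                                                      "start", "end")])
    jc_mat <- matrix(rpois(nrow(jx) * length(samples), lambda = 30),
                     nrow = nrow(jx))
    junction_counts <- dplyr::bind_cols(
      jx, as_tibble(as.data.frame(jc_mat), .name_repair = ~samples))

    event_classes <- tibble(
      event_id = paste0(truth$transcript_id, ":", truth$intron_start, "-",
                        truth$intron_end),
      klass = truth$klass)
    conc <- spec$pso_plan$concentration
    psi_mat <- matrix(NA_real_, nrow = nrow(truth), ncol = length(samples))
    for (i in seq_len(nrow(truth))) {
      means <- spec$pso_plan[[truth$klass[i]]]
      pso_mean <- means[sample_sheet$condition]
      draws <- rbeta(length(samples), pso_mean * conc,
                     (1 - pso_mean) * conc)
      psi_mat[i, ] <- round(1 - draws, 6)
    }
    psi <- dplyr::bind_cols(
      tibble(event_id = event_classes$event_id),
      as_tibble(as.data.frame(psi_mat), .name_repair = ~samples))
    list(genome = genome, tpm = tpm, junction_counts = junction_counts,
         psi = psi, event_classes = event_classes)
  })

  fixture <- structure(
    list(spec = spec, genome = out$genome, reference = reference,
         assembly = assembly, truth = truth, decoys = decoys,
         tpm = out$tpm,
         tx2gene = tibble(transcript_id = assembly$transcript_id,
                          gene_id = assembly$gene_id),
         junction_counts = out$junction_counts, psi = out$psi,
         event_classes = out$event_classes, sample_sheet = sample_sheet),
    class = "utr_fixture")

  if (!is.null(outdir)) {
    fixture$paths <- write_fixture(fixture, outdir)
  }
  fixture
}

write_fixture <- function(fixture, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    reference = file.path(outdir, "reference.gtf"),
    assembly = file.path(outdir, "assembly.gtf"),
    tpm = file.path(outdir, "tpm.tsv"),
    junction_counts = file.path(outdir, "junction_counts.tsv"),
    psi = file.path(outdir, "psi.tsv"),
    sample_sheet = file.path(outdir, "sample_sheet.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    decoys = file.path(outdir, "decoys.tsv"),
    manifest = file.path(outdir, "manifest.txt"))
  Biostrings::writeXStringSet(fixture$genome, paths$genome, width = 80)
  write_gtf(fixture$reference, paths$reference)
  write_gtf(fixture$assembly, paths$assembly)
  tsv <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(fixture$tpm, paths$tpm)
  tsv(fixture$junction_counts, paths$junction_counts)
  tsv(fixture$psi, paths$psi)
  tsv(fixture$sample_sheet, paths$sample_sheet)
  tsv(fixture$truth, paths$truth)
  tsv(fixture$decoys, paths$decoys)
  writeLines(c(paste("seed", fixture$spec$seed),
               paste("n_genes", fixture$spec$n_genes),
               paste("n_samples", nrow(fixture$sample_sheet)),
               paste("n_truth_introns", nrow(fixture$truth))),
             paths$manifest)
  paths
}

#' Expression tables with a planted PSO-correlated regulator
#'
#' Generates a gene-level count matrix in which one regulator gene's
#' expression tracks the per-sample mean e3UI PSO at a target Spearman
#' correlation per condition (via a Gaussian rank copula), alongside
#' independent background genes. Defaults for the targets mirror a strong
#' negative normal-tissue association that is lost in cancer.
#'
#' @param fixture A `utr_fixture` (provides PSI draws, event classes and the
#'   sample sheet).
#' @param n_background Number of uncorrelated background genes (default 40).
#' @param rho_normal,rho_cancer Target Spearman correlations; taken from the
#'   fixture's regulator plan when `NULL`.
#' @param seed Seed for the draws; defaults to the fixture seed + 2.
#' @return A list with `counts` (tibble `gene_id` x samples of integer
#'   counts; the regulator is gene `REGULATOR`) and `mean_pso` (per-sample
#'   mean e3UI PSO used as the anchor).
#' @export
make_correlated_quant <- function(fixture, n_background = 40,
                                  rho_normal = NULL, rho_cancer = NULL,
                                  seed = NULL) {
  stopifnot(inherits(fixture, "utr_fixture"))
  rho_normal <- rho_normal %||% fixture$spec$regulator$rho_normal
  rho_cancer <- rho_cancer %||% fixture$spec$regulator$rho_cancer
  for (r in c(rho_normal, rho_cancer)) {
    if (abs(r) >= 1) {
      abort("target correlations must lie in (-1, 1)",
            class = "utrintrons_validation_error")
    }
  }
  seed <- seed %||% (fixture$spec$seed + 2L)
  pso <- pso_from_psi(fixture$psi)
  summ <- sample_average_pso(pso, fixture$event_classes,
                             fixture$sample_sheet)
  summ <- summ[summ$klass == "e3UI", ]
  mean_pso <- setNames(summ$mean_pso, summ$sample)
  sheet <- fixture$sample_sheet
  samples <- sheet$sample

  with_preserved_seed(seed, {
    reg <- numeric(length(samples))
    names(reg) <- samples
    for (cond in unique(sheet$condition)) {
      rho <- if (cond == "cancer") rho_cancer else rho_normal
      cs <- sheet$sample[sheet$condition == cond]
      reg[cs] <- copula_correlate(mean_pso[cs], rho)
    }
    reg_counts <- round(exp(log(500) + 0.5 * reg))
    bg <- matrix(round(stats::rlnorm(n_background * length(samples),
                                     meanlog = log(300), sdlog = 0.6)),
                 nrow = n_background, ncol = length(samples))
    counts <- rbind(matrix(reg_counts, nrow = 1), bg)
    counts_tbl <- dplyr::bind_cols(
      tibble(gene_id = c("REGULATOR",
                         sprintf("BG%03d", seq_len(n_background)))),
      as_tibble(as.data.frame(counts), .name_repair = ~samples))
    list(counts = counts_tbl, mean_pso = mean_pso)
  })
}

# Gaussian rank copula: returns a standard-normal-scale vector whose Spearman
# correlation with `anchor` targets `rho` (Pearson-Spearman conversion
# 2*sin(pi*rho/6) for the latent bivariate normal).
copula_correlate <- function(anchor, rho) {
  n <- length(anchor)
  u <- (rank(anchor, ties.method = "average") - 0.5) / n
  x <- qnorm(u)
  rho_p <- 2 * sin(pi * rho / 6)
  rho_p * x + sqrt(1 - rho_p^2) * rnorm(n)
}
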