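toy_quant <- function() {
  tpm <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    s1 = c(5, 15, 0),
    s2 = c(2, 0.5, 0))
  tx2gene <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                            gene_id = c("g1", "g1", "g2"))
  quant_table(tpm, tx2gene)
}

test_that("gene totals conserve transcript TPM and fractions follow", {
  q <- toy_quant()
  expect_equal(fraction_expression(q, "t1", "s1"), 0.25)
  expect_equal(fraction_expression(q, "t2", "s1"), 0.75)
  # sole expressed transcript of its gene
  expect_equal(fraction_expression(q, "t1", "s2"), 0.8)
  # zero gene total -> missing
  expect_true(is.na(fraction_expression(q, "t3", "s1")))
  expect_error(fraction_expression(q, "nope", "s1"),
               class = "utrintrons_lookup_error")
  sums <- q |>
    dplyr::group_by(gene_id, sample) |>
    dplyr::summarise(total = sum(tpm), gene = dplyr::first(gene_tpm),
                     .groups = "drop")
  expect_equal(sums$total, sums$gene)
})

test_that("expressed calls use strict TPM and fraction thresholds", {
  tpm <- tibble::tibble(transcript_id = c("a", "b"),
                        s1 = c(2, 2), s2 = c(2, 1.0), s3 = c(1.01, 8))
  tx2gene <- tibble::tibble(transcript_id = c("a", "b"),
                            gene_id = c("g", "g"))
  q <- quant_table(tpm, tx2gene)
  expect_true(is_expressed(q, "a", "s1"))    # tpm 2, fraction 0.5
  expect_true(is_expressed(q, "a", "s2"))    # tpm 2, fraction 2/3
  expect_false(is_expressed(q, "b", "s2"))   # tpm exactly 1: strict
  expect_false(is_expressed(q, "a", "s3"))   # fraction 1.01/9.01 < 0.25
  # fraction exactly at the threshold is excluded
  tpm2 <- tibble::tibble(transcript_id = c("a", "b"), s1 = c(2, 6))
  q2 <- quant_table(tpm2, tx2gene)
  expect_equal(fraction_expression(q2, "a", "s1"), 0.25)
  expect_false(is_expressed(q2, "a", "s1"))
})

broad_setup <- function(n_normal = 20, n_cancer = 20, expressed_cancer = 3,
                        junction_total = 1) {
  samples <- c(sprintf("n%02d", seq_len(n_normal)),
               sprintf("c%02d", seq_len(n_cancer)))
  sheet <- tibble::tibble(
    sample = samples,
    condition = rep(c("normal", "cancer"), c(n_normal, n_cancer)))
  tpm_vals <- stats::setNames(rep(0.1, length(samples)), samples)
  if (expressed_cancer > 0) {
    tpm_vals[sprintf("c%02d", seq_len(expressed_cancer))] <- 10
  }
  tpm <- dplyr::bind_cols(tibble::tibble(transcript_id = "tx"),
                          tibble::as_tibble(as.list(tpm_vals)))
  q <- quant_table(tpm, tibble::tibble(transcript_id = "tx",
                                       gene_id = "g"))
  jx <- tibble::tibble(transcript_id = "tx", chrom = "chr1", strand = "+",
                       start = 100L, end = 200L)
  counts <- rep(0, length(samples))
  counts[1] <- junction_total
  jc <- dplyr::bind_cols(
    tibble::tibble(chrom = "chr1", strand = "+", start = 100L, end = 200L),
    tibble::as_tibble(as.list(stats::setNames(counts, samples))))
  list(q = q, jc = jc, jx = jx, sheet = sheet)
}

test_that("broad expression needs 10% of one condition plus junction coverage", {
  s <- broad_setup(expressed_cancer = 3)  # 15% of cancer samples
  out <- broadly_expressed(s$q, s$jc, s$jx, s$sheet)
  expect_true(out$broadly_expressed)
  expect_equal(out$frac_cancer, 0.15)

  s2 <- broad_setup(expressed_cancer = 1)  # 5%: below the ceiling(2) cut
  out2 <- broadly_expressed(s2$q, s2$jc, s2$jx, s2$sheet)
  expect_false(out2$broadly_expressed)

  # well expressed but one junction with zero reads everywhere
  s3 <- broad_setup(expressed_cancer = 10, junction_total = 0)
  out3 <- broadly_expressed(s3$q, s3$jc, s3$jx, s3$sheet)
  expect_false(out3$broadly_expressed)
  expect_false(out3$junctions_covered)

  # the count threshold is a ceiling: 10% of 25 samples means >= 3
  s4 <- broad_setup(n_cancer = 25, expressed_cancer = 2)
  expect_false(broadly_expressed(s4$q, s4$jc, s4$jx,
                                 s4$sheet)$broadly_expressed)
  s5 <- broad_setup(n_cancer = 25, expressed_cancer = 3)
  expect_true(broadly_expressed(s5$q, s5$jc, s5$jx,
                                s5$sheet)$broadly_expressed)
})

test_that("coverage is monotone and labels can be permuted within condition", {
  s <- broad_setup(expressed_cancer = 3, junction_total = 0)
  base <- broadly_expressed(s$q, s$jc, s$jx, s$sheet)
  expect_false(base$broadly_expressed)
  jc_more <- s$jc
  jc_more$c01 <- jc_more$c01 + 5
  expect_true(broadly_expressed(s$q, jc_more, s$jx,
                                s$sheet)$broadly_expressed)

  s6 <- broad_setup(expressed_cancer = 4)
  ref <- broadly_expressed(s6$q, s6$jc, s6$jx, s6$sheet)
  sheet_perm <- s6$sheet
  set.seed(1)
  for (cond in unique(sheet_perm$condition)) {
    i <- which(sheet_perm$condition == cond)
    sheet_perm$sample[i] <- sample(sheet_perm$sample[i])
  }
  perm <- broadly_expressed(s6$q, s6$jc, s6$jx, sheet_perm)
  expect_equal(ref$broadly_expressed, perm$broadly_expressed)
  expect_equal(ref$frac_cancer, perm$frac_cancer)
})

test_that("unlabelled samples are an error", {
  s <- broad_setup()
  sheet_bad <- s$sheet[-1, ]
  expect_error(broadly_expressed(s$q, s$jc, s$jx, sheet_bad),
               class = "utrintrons_lookup_error")
})
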