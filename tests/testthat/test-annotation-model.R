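gtf_line <- function(chrom, feature, start1, end1, strand, attrs) {
  paste(chrom, "test", feature, start1, end1, ".", strand, ".", attrs,
        sep = "\t")
}

tx_attrs <- function(tx = "t1", gene = "g1", extra = "") {
  paste0('gene_id "', gene, '"; transcript_id "', tx, '";', extra)
}

test_that("GTF coordinates convert to 0-based half-open and exon order is irrelevant", {
  f1 <- withr::local_tempfile(fileext = ".gtf")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  lines <- c(gtf_line("chr1", "exon", 101, 200, "+", tx_attrs()),
             gtf_line("chr1", "exon", 301, 400, "+", tx_attrs()),
             gtf_line("chr1", "stop_codon", 391, 393, "+", tx_attrs()))
  writeLines(lines, f1)
  writeLines(rev(lines), f2)
  m1 <- transcript_models(read_gtf(f1))
  m2 <- transcript_models(read_gtf(f2))
  expect_equal(m1$exons[[1]], cbind(c(100L, 300L), c(200L, 400L)),
               ignore_attr = TRUE)
  expect_equal(m1$stop_start, 390L)
  expect_equal(m1$stop_end, 393L)
  expect_equal(m1$exons[[1]], m2$exons[[1]])
})

test_that("malformed GTF lines are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "exon", 1, 50, "+", tx_attrs()),
               "chr1\tbroken line"), f)
  expect_error(read_gtf(f), "line 2", class = "utrintrons_parse_error")
})

test_that("overlapping exons within a transcript are rejected", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "exon", 1, 100, "+", tx_attrs()),
               gtf_line("chr1", "exon", 50, 150, "+", tx_attrs())), f)
  expect_error(transcript_models(read_gtf(f)), "overlapping",
               class = "utrintrons_validation_error")
})

test_that("intron chains are the gaps between sorted exons", {
  m <- mk_models(
    mk_tx("two", list(c(100, 200), c(300, 400))),
    mk_tx("one", list(c(100, 400))),
    mk_tx("three", list(c(0, 10), c(20, 30), c(40, 50))))
  ti <- transcript_introns(m)
  expect_equal(ti$intron_start[ti$transcript_id == "two"], 200L)
  expect_equal(ti$intron_end[ti$transcript_id == "two"], 300L)
  expect_false("one" %in% ti$transcript_id)
  th <- ti[ti$transcript_id == "three", ]
  expect_equal(th$intron_start, c(10L, 30L))
  expect_equal(th$intron_end, c(20L, 40L))
})

test_that("stop codons derive from the CDS 3' end by an exonic walk", {
  explicit <- mk_tx("e", list(c(100, 500)), stop = c(390, 393))
  expect_equal(stop_codon_of(explicit, "e"), list(start = 390L, end = 393L,
                                                  split = FALSE))
  plus <- mk_tx("p", list(c(100, 500)), cds = list(c(120, 390)))
  expect_equal(stop_codon_of(plus, "p")[c("start", "end")],
               list(start = 390L, end = 393L))
  minus <- mk_tx("m", list(c(50, 500)), strand = "-",
                 cds = list(c(100, 400)))
  expect_equal(stop_codon_of(minus, "m")[c("start", "end")],
               list(start = 97L, end = 100L))
  split <- mk_tx("s", list(c(100, 200), c(300, 400)),
                 cds = list(c(120, 199)))
  sc <- stop_codon_of(split, "s")
  expect_equal(sc$start, 199L)
  expect_equal(sc$end, 302L)
  expect_true(sc$split)
})

test_that("stop derivation errors are specific", {
  no_cds <- mk_tx("n", list(c(100, 200)))
  expect_error(stop_codon_of(no_cds, "n"), class = "utrintrons_stop_error")
  short <- mk_tx("sh", list(c(100, 200)), cds = list(c(120, 199)))
  expect_error(stop_codon_of(short, "sh"), class = "utrintrons_stop_error")
})

test_that("spliced distance counts exonic bases only and is symmetric", {
  m <- mk_tx("t", list(c(100, 200), c(300, 400)))
  expect_equal(spliced_distance(m, "t", 110, 120), 10L)
  expect_equal(spliced_distance(m, "t", 195, 305), 10L)
  expect_equal(spliced_distance(m, "t", 305, 195), 10L)
  expect_equal(spliced_distance(m, "t", 150, 150), 0L)
  expect_error(spliced_distance(m, "t", 250, 300),
               class = "utrintrons_coordinate_error")
})

test_that("spliced distance is bounded by genomic distance and survives mirroring", {
  set.seed(42)
  for (rep in 1:20) {
    n_ex <- sample(1:4, 1)
    bounds <- sort(sample(0:999, 2 * n_ex))
    exons <- lapply(seq_len(n_ex), function(i) bounds[c(2 * i - 1, 2 * i)])
    exons <- purrr::keep(exons, ~.x[2] > .x[1])
    if (length(exons) == 0) next
    m <- mk_tx("t", exons)
    ex <- m$exons[[1]]
    a <- sample(seq(ex[1, 1], ex[1, 2] - 1), 1)
    last <- nrow(ex)
    b <- sample(seq(ex[last, 1], ex[last, 2] - 1), 1)
    d <- spliced_distance(m, "t", a, b)
    expect_lte(d, abs(b - a))
    L <- 2000L
    mm <- reflect_models(m, L)
    expect_equal(spliced_distance(mm, "t", L - 1L - a, L - 1L - b), d)
    ti <- transcript_introns(m)
    tm <- transcript_introns(mm)
    expect_equal(sort(ti$intron_end - ti$intron_start),
                 sort(tm$intron_end - tm$intron_start))
  }
})

test_that("write/read round trip preserves coordinates and attributes", {
  m <- mk_models(
    mk_tx("rt1", list(c(100, 200), c(300, 400)), gene = "g",
          cds = list(c(120, 200), c(300, 330)), stop = c(330, 333),
          tsl = "1", appris = "appris_principal_1",
          biotype = "protein_coding"),
    mk_tx("rt2", list(c(1000, 1200)), gene = "g2", strand = "-", tsl = "5"))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(m, f)
  back <- transcript_models(read_gtf(f))
  back <- back[match(m$transcript_id, back$transcript_id), ]
  expect_equal(back$exons, m$exons, ignore_attr = TRUE)
  expect_equal(back$cds_start, m$cds_start)
  expect_equal(back$cds_end, m$cds_end)
  expect_equal(back$stop_start, m$stop_start)
  expect_equal(back$stop_end, m$stop_end)
  expect_equal(back$tsl, m$tsl)
  expect_equal(back$appris, m$appris)
})
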