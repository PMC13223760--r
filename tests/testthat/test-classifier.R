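# Shared toy locus: reference with 1 CDS intron and an early-PTC isoform.
toy_refs <- function() {
  mk_models(
    # main isoform: CDS intron (160, 250), stop at (310, 313)
    mk_tx("R_MAIN", list(c(0, 160), c(250, 700)), gene = "g",
          cds = list(c(100, 160), c(250, 310)), stop = c(310, 313),
          tsl = "1", appris = "appris_principal_1"),
    # early-PTC isoform: same chain, stop at (130, 133): the CDS intron of
    # R_MAIN is downstream of this stop
    mk_tx("R_PTC", list(c(0, 160), c(250, 700)), gene = "g",
          cds = list(c(100, 130)), stop = c(130, 133),
          tsl = "1", appris = "appris_principal_1"),
    # spliced 3' UTR isoform: carries the post-stop intron (400, 500)
    mk_tx("R_UTR", list(c(0, 160), c(250, 400), c(500, 700)), gene = "g",
          cds = list(c(100, 160), c(250, 310)), stop = c(310, 313),
          tsl = "5"))
}

test_that("candidate references need same strand and an exonic start codon", {
  refs <- toy_refs()
  hc <- filter_high_confidence(refs)
  q <- mk_tx("q", list(c(0, 160), c(250, 700)), gene = "g")
  expect_setequal(candidate_references(q, "q", hc)$transcript_id,
                  c("R_MAIN", "R_PTC"))
  anti <- mk_tx("a", list(c(0, 700)), gene = "g", strand = "-")
  expect_equal(nrow(candidate_references(anti, "a", hc)), 0)
  # start codon (position 100) inside the query's intron
  gap <- mk_tx("gp", list(c(0, 90), c(140, 700)), gene = "g")
  expect_equal(nrow(candidate_references(gap, "gp", hc)), 0)
})

test_that("CDS chain match compares intron sets over the reference CDS span", {
  refs <- toy_refs()
  match_q <- mk_tx("m", list(c(0, 160), c(250, 700)))
  expect_true(cds_chain_match(match_q, "m", refs, "R_MAIN"))
  retained <- mk_tx("r", list(c(0, 700)))
  expect_false(cds_chain_match(retained, "r", refs, "R_MAIN"))
  extra <- mk_tx("x", list(c(0, 160), c(250, 280), c(290, 700)))
  expect_false(cds_chain_match(extra, "x", refs, "R_MAIN"))
  # the retained query still matches the early-PTC isoform (no introns in its
  # CDS span)
  expect_true(cds_chain_match(retained, "r", refs, "R_PTC"))
})

test_that("UTR introns are those with donors strictly past the stop codon", {
  refs <- toy_refs()
  q <- mk_tx("q", list(c(0, 160), c(250, 400), c(500, 700)))
  ui <- utr_introns(q, "q", refs, "R_MAIN")
  expect_equal(nrow(ui), 1)
  expect_equal(ui[1, ], c(400L, 500L), ignore_attr = TRUE)
  # the CDS intron's donor precedes the stop: excluded
  expect_false(any(ui[, 1] == 160))
  no_ui <- mk_tx("n", list(c(0, 160), c(250, 700)))
  expect_equal(nrow(utr_introns(no_ui, "n", refs, "R_MAIN")), 0)
})

test_that("classification separates e3UI from co3UI and annotated from novel", {
  refs <- toy_refs()
  hc <- filter_high_confidence(refs)
  idx <- reference_indices(refs, hc)
  queries <- mk_models(
    # annotated 3UI: same junction as R_UTR
    mk_tx("q_e3", list(c(0, 160), c(250, 400), c(500, 700)), gene = "g"),
    # novel 3UI at a different position
    mk_tx("q_nov", list(c(0, 160), c(250, 420), c(520, 700)), gene = "g"))
  rec <- classify_utr_introns(queries, hc, idx)
  e3 <- rec[rec$transcript_id == "q_e3", ]
  # matched against both R_MAIN and R_PTC; against R_PTC the old CDS intron
  # (160, 250) is also post-stop and shares boundaries with a coding intron
  expect_setequal(e3$matched_reference_id, c("R_MAIN", "R_PTC"))
  utr_rec <- e3[e3$intron_start == 400, ]
  expect_true(all(utr_rec$klass == "e3UI"))
  expect_true(all(!utr_rec$novel))
  cds_rec <- e3[e3$intron_start == 160, ]
  expect_equal(cds_rec$matched_reference_id, "R_PTC")
  expect_equal(cds_rec$klass, "co3UI")
  nov <- rec[rec$transcript_id == "q_nov" & rec$intron_start == 420, ]
  expect_true(all(nov$klass == "e3UI"))
  expect_true(all(nov$novel))
})

test_that("distances follow the spliced path from each matched stop codon", {
  refs <- toy_refs()
  hc <- filter_high_confidence(refs)
  idx <- reference_indices(refs, hc)
  q <- mk_tx("q", list(c(0, 160), c(250, 400), c(500, 700)), gene = "g")
  rec <- classify_utr_introns(q, hc, idx)
  utr_rec <- rec[rec$intron_start == 400, ]
  # vs R_MAIN stop (310,313): exonic bases 313..399 -> 87
  expect_equal(utr_rec$distance_to_stop[
    utr_rec$matched_reference_id == "R_MAIN"], 87L)
  # vs R_PTC stop (130,133): 133..159 (27) + 250..399 (150) = 177
  expect_equal(utr_rec$distance_to_stop[
    utr_rec$matched_reference_id == "R_PTC"], 177L)
  # the same intron relative to the PTC stop: donor at 160, bases 133..159
  expect_equal(rec$distance_to_stop[rec$intron_start == 160], 27L)
})

test_that("a dual-stop locus reproduces the 8/135 nt pattern", {
  # two retained-intron references whose stops sit 8 and 135 exonic nt
  # upstream of a common 3UI donor
  donor <- 800L
  refs <- mk_models(
    mk_tx("R_NEAR", list(c(0, 1100)), gene = "g",
          cds = list(c(10, donor - 8 - 3)), stop = c(donor - 8 - 3, donor - 8),
          tsl = "1", appris = "appris_principal_1"),
    mk_tx("R_FAR", list(c(0, 1100)), gene = "g",
          cds = list(c(10, donor - 135 - 3)),
          stop = c(donor - 135 - 3, donor - 135),
          tsl = "1", appris = "appris_principal_1"))
  hc <- filter_high_confidence(refs)
  idx <- reference_indices(refs, hc)
  q <- mk_tx("q", list(c(0, donor), c(donor + 90, 1100)), gene = "g")
  rec <- classify_utr_introns(q, hc, idx)
  expect_equal(sort(rec$distance_to_stop), c(8L, 135L))
  expect_equal(max_distance(rec), 135L)
  expect_equal(rec$matched_reference_id[rec$max_distance_flag], "R_FAR")
  nmd <- nmd_expectation(rec$distance_to_stop)
  expect_equal(nmd$expected_sensitive[nmd$distance == 8], FALSE)
  expect_equal(nmd$expected_sensitive[nmd$distance == 135], TRUE)
})

test_that("a shared-donor locus reproduces the common 15 nt donor pattern", {
  # one stop codon, two alternative acceptors for a donor 15 nt downstream
  refs <- mk_models(
    mk_tx("R", list(c(0, 1200)), gene = "g",
          cds = list(c(10, 482)), stop = c(482, 485),
          tsl = "1", appris = "appris_principal_1"))
  hc <- filter_high_confidence(refs)
  idx <- reference_indices(refs, hc)
  donor <- 500L
  queries <- mk_models(
    mk_tx("short_sp", list(c(0, donor), c(donor + 305, 1200)), gene = "g"),
    mk_tx("long_sp", list(c(0, donor), c(donor + 464, 1200)), gene = "g"))
  rec <- classify_utr_introns(queries, hc, idx)
  expect_equal(rec$distance_to_stop, c(15L, 15L))
  lens <- setNames(rec$intron_end - rec$intron_start, rec$transcript_id)
  expect_equal(lens[["short_sp"]], 305L)
  expect_equal(lens[["long_sp"]], 464L)
  expect_true(all(rec$klass == "e3UI"))
})

test_that("the NMD rule boundary is strict at the threshold", {
  nmd <- nmd_expectation(c(8, 55, 56, 135))
  expect_equal(nmd$expected_sensitive, c(FALSE, FALSE, TRUE, TRUE))
  nmd50 <- nmd_expectation(c(50, 51), threshold = 50)
  expect_equal(nmd50$expected_sensitive, c(FALSE, TRUE))
  expect_error(nmd_expectation(-1), class = "utrintrons_validation_error")
})

test_that("the maximal distance record is flagged, with deterministic ties", {
  refs <- mk_models(
    mk_tx("R", list(c(0, 2000)), gene = "g",
          cds = list(c(10, 97)), stop = c(97, 100),
          tsl = "1", appris = "appris_principal_1"))
  hc <- filter_high_confidence(refs)
  idx <- reference_indices(refs, hc)
  q <- mk_tx("q", list(c(0, 155), c(255, 310), c(410, 2000)), gene = "g")
  rec <- classify_utr_introns(q, hc, idx)
  expect_equal(rec$distance_to_stop, c(55L, 110L))
  expect_equal(max_distance(rec), 110L)
  expect_true(rec$max_distance_flag[rec$intron_start == 310])
  expect_false(rec$max_distance_flag[rec$intron_start == 155])
  expect_error(max_distance(rec[0, ]), class = "utrintrons_validation_error")

  # equal distances from two identical references: exactly one flag,
  # assigned by reference id
  refs2 <- mk_models(
    mk_tx("R_A", list(c(0, 2000)), gene = "g",
          cds = list(c(10, 97)), stop = c(97, 100),
          tsl = "1", appris = "appris_principal_1"),
    mk_tx("R_B", list(c(0, 2000)), gene = "g",
          cds = list(c(10, 97)), stop = c(97, 100),
          tsl = "1", appris = "appris_principal_1"))
  hc2 <- filter_high_confidence(refs2)
  idx2 <- reference_indices(refs2, hc2)
  rec2 <- classify_utr_introns(mk_tx("q", list(c(0, 155), c(255, 2000)),
                                     gene = "g"), hc2, idx2)
  expect_equal(sum(rec2$max_distance_flag), 1)
  expect_equal(rec2$matched_reference_id[rec2$max_distance_flag], "R_A")
})

test_that("classification is invariant to input order and to locus mirroring", {
  spec <- fixture_spec(n_genes = 8, seed = 11)
  fx <- make_fixture(spec)
  hc <- filter_high_confidence(fx$reference)
  idx <- reference_indices(fx$reference, hc)
  rec_fwd <- classify_utr_introns(fx$assembly, hc, idx)
  shuffle <- fx$assembly[sample(nrow(fx$assembly)), ]
  rec_shuf <- classify_utr_introns(shuffle, hc, idx)
  expect_equal(record_key(rec_fwd), record_key(rec_shuf))

  L <- length(fx$genome[[1]])
  refs_m <- reflect_models(fx$reference, L)
  asm_m <- reflect_models(fx$assembly, L)
  hc_m <- filter_high_confidence(refs_m)
  idx_m <- reference_indices(refs_m, hc_m)
  rec_mir <- classify_utr_introns(asm_m, hc_m, idx_m)
  expect_equal(record_key(unreflect_records(rec_mir, L)),
               record_key(rec_fwd))
})

test_that("the optimized classifier agrees with the brute-force oracle", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    idx <- reference_indices(inst$refs, inst$refs_hc)
    rec <- classify_utr_introns(inst$query, inst$refs_hc, idx)
    oracle <- oracle_classify(inst$query, inst$refs_hc, inst$refs)
    expect_equal(record_key(rec), record_key(oracle), label = paste("seed", seed))
  }
})
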