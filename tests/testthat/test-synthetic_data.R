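test_that("identical seeds give byte-identical simulation outputs", {
  cfg <- basic_sim_config(seed = 19, n = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateERVGenome(cfg, outDir = d1)
  simulateERVGenome(cfg, outDir = d2)
  for (f in c("genome.fa", "annotations.bed", "trnas.fa", "truth.tsv",
              "families.cfg"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # a different seed changes the genome
  cfg2 <- basic_sim_config(seed = 20, n = 8)
  d3 <- withr::local_tempdir()
  simulateERVGenome(cfg2, outDir = d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("variant frequencies must sum to 1; indels must be interior", {
  expect_error(simulationConfig(families = list(list(
    name = "F", nElements = 5, primer = "p",
    variants = list(list(name = "a", edits = NULL, freq = 0.5))))),
    "sum to 1")
  expect_error(simulationConfig(families = list(list(
    name = "F", nElements = 5, primer = "p",
    variants = list(list(name = "a",
                         edits = data.frame(op = "del", pos = 18,
                                            base = ""),
                         freq = 1))))),
    "interior")
})

test_that("assembly recovers all planted elements without fragmentation", {
  cfg <- basic_sim_config(seed = 33, n = 50)
  sim <- simulateERVGenome(cfg)
  feats <- sim$annotations[!is.na(sim$annotations$family)]
  el <- callElements(mergeFragments(feats), sim$genome, "FamA")$elements
  expect_length(el, 50L)
  calls <- locatePBS(el, sim$trnas)
  ev <- evaluateRecovery(el, calls, sim$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$variant_count_error, 0L)
})

test_that("decoy-only input yields zero elements and lists solo LTRs", {
  cfg <- simulationConfig(
    seed = 37,
    families = list(list(name = "FamA", nElements = 0,
                         primer = "Lys3-UUU")),
    ltrLen = 600L, internalLen = 800L,
    decoys = list(solo_ltr = 4L, internal_only = 2L, short_fragment = 3L))
  sim <- simulateERVGenome(cfg)
  feats <- sim$annotations[!is.na(sim$annotations$family)]
  cl <- mergeFragments(feats)
  res <- callElements(cl, sim$genome, "FamA")
  expect_length(res$elements, 0L)
  # the four solo LTRs (>=500 nt, LTR-only clusters) are reported
  expect_length(soloLtrs(cl), 4L + 3L) # short LTR pieces are LTR-only too
  expect_equal(unname(res$log[["dropped_short"]]), 3L)
  expect_equal(unname(res$log[["dropped_missing_ltr"]]),
               4L + 2L)
})

test_that("annotation gaps beyond the merge limit break only that element", {
  cfg <- basic_sim_config(seed = 39, n = 12, frag_prob = 1,
                          gap_range = c(501L, 501L))
  sim <- simulateERVGenome(cfg)
  expect_true(all(!sim$truth$expected_survival))
  feats <- sim$annotations[!is.na(sim$annotations$family)]
  el <- callElements(mergeFragments(feats), sim$genome, "FamA")$elements
  expect_length(el, 0L)
  # sub-limit gaps leave every element recoverable at truth coordinates
  cfg2 <- basic_sim_config(seed = 39, n = 12, frag_prob = 1,
                           gap_range = c(100L, 500L))
  sim2 <- simulateERVGenome(cfg2)
  expect_true(all(sim2$truth$expected_survival))
  feats2 <- sim2$annotations[!is.na(sim2$annotations$family)]
  el2 <- callElements(mergeFragments(feats2), sim2$genome, "FamA")$elements
  ev <- evaluateRecovery(el2, locatePBS(el2, sim2$trnas), sim2$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$variant_count_error, 0L)
})

test_that("planted primer-switch fraction is assigned exactly", {
  cfg <- simulationConfig(
    seed = 41,
    families = list(list(
      name = "FamA", nElements = 100, primer = "Lys3-UUU",
      altPrimer = "Lys1/2-CUU", switchFraction = 0.3,
      variants = list(list(name = "perfect", edits = NULL, freq = 1)))),
    ltrLen = 300L, internalLen = 600L)
  sim <- simulateERVGenome(cfg)
  expect_equal(sum(sim$truth$primer == "Lys1/2-CUU"), 30L)
  feats <- sim$annotations[!is.na(sim$annotations$family)]
  el <- callElements(mergeFragments(feats), sim$genome, "FamA")$elements
  calls <- locatePBS(el, sim$trnas)
  ev <- evaluateRecovery(el, calls, sim$truth)
  expect_equal(ev$primer_accuracy, 1)
  expect_equal(mean(calls$primer_assigned == "Lys1/2-CUU"), 0.3)
})

test_that("minus-strand planting is recovered identically", {
  cfg <- simulationConfig(
    seed = 47,
    families = list(list(
      name = "FamA", nElements = 20, primer = "Lys3-UUU",
      variants = list(list(name = "perfect", edits = NULL, freq = 1)))),
    ltrLen = 300L, internalLen = 600L, minusStrandFraction = 0.5)
  sim <- simulateERVGenome(cfg)
  expect_equal(sum(sim$truth$strand == "-"), 10L)
  feats <- sim$annotations[!is.na(sim$annotations$family)]
  el <- callElements(mergeFragments(feats), sim$genome, "FamA")$elements
  calls <- locatePBS(el, sim$trnas)
  ev <- evaluateRecovery(el, calls, sim$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$pbs_seq_accuracy, 1)
})
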