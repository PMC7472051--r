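test_that("fragments merge within the gap limit, on the same strand only", {
  # gaps of 50 < 500: one cluster of 3 (0-based gaps: 1400-1350, 5450-5400)
  gr <- frag_gr("chr1", c(1001, 1401, 5451), c(1350, 5400, 5800), "+",
                c("L", "I", "L"), c("LTR", "internal", "LTR"))
  cl <- mergeFragments(gr, maxGap = 500)
  expect_length(cl, 1L)
  expect_length(cl[[1]], 3L)
  # gap of 550 > 500: two clusters
  gr2 <- frag_gr("chr1", c(1001, 1901), c(1350, 5400), "+",
                 c("L", "I"), c("LTR", "internal"))
  expect_length(mergeFragments(gr2, maxGap = 500), 2L)
  # gap of exactly 500 merges (<= limit)
  gr3 <- frag_gr("chr1", c(1001, 1851), c(1350, 5400), "+",
                 c("L", "I"), c("LTR", "internal"))
  expect_length(mergeFragments(gr3, maxGap = 500), 1L)
  # same intervals, internal on the minus strand: never merged
  gr4 <- frag_gr("chr1", c(1001, 1401), c(1350, 5400), c("+", "-"),
                 c("L", "I"), c("LTR", "internal"))
  expect_length(mergeFragments(gr4, maxGap = 500), 2L)
  # different chromosomes: never merged
  gr5 <- frag_gr(c("chr1", "chr2"), c(1001, 1401), c(1350, 5400), "+",
                 c("L", "I"), c("LTR", "internal"))
  expect_length(mergeFragments(gr5, maxGap = 500), 2L)
})

test_that("overlapping and nested fragments always merge", {
  gr <- frag_gr("chr1", c(1001, 1200, 1250), c(1500, 1400, 2600), "+",
                c("L", "I", "I"), c("LTR", "internal", "internal"))
  expect_length(mergeFragments(gr, maxGap = 0), 1L)
})

test_that("merging is idempotent and partitions the input", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    gr <- frag_gr("chr1",
                  start <- sort(sample(1:20000, n)),
                  start + sample(100:900, n, replace = TRUE),
                  sample(c("+", "-"), n, replace = TRUE),
                  paste0("f", 1:n),
                  sample(c("LTR", "internal"), n, replace = TRUE))
    cl <- mergeFragments(gr, maxGap = 500)
    # partition: every feature appears exactly once
    flat <- unlist(cl, use.names = FALSE)
    expect_equal(sort(flat$repeat_name), sort(gr$repeat_name))
    # idempotence: re-merging each cluster yields the cluster itself
    for (g in as.list(cl))
      expect_length(mergeFragments(g, maxGap = 500), 1L)
  }
})

test_that("solo-LTR clusters are reported; mixed clusters are not", {
  roles <- c("LTR", "internal")
  # enumerate all 3-fragment role combinations within one cluster
  for (r1 in roles) for (r2 in roles) for (r3 in roles) {
    rr <- c(r1, r2, r3)
    gr <- frag_gr("chr1", c(1001, 1501, 2001), c(1400, 1900, 2400), "+",
                  paste0("f", 1:3), rr)
    cl <- mergeFragments(gr, maxGap = 500)
    solo <- soloLtrs(cl)
    if (all(rr == "LTR")) expect_length(solo, 3L)
    else expect_length(solo, 0L)
  }
  # two lone LTRs 100 bp apart, no internal: one solo cluster, both listed
  gr <- frag_gr("chr1", c(1001, 1451), c(1350, 1800), "+",
                c("L", "L"), c("LTR", "LTR"))
  expect_length(soloLtrs(mergeFragments(gr, maxGap = 500)), 2L)
})

test_that("elements require min span and both flanking LTRs", {
  toy <- toy_element_genome("TGGACGTACGTACGTACG")
  cl <- mergeFragments(toy$annotations)
  res <- callElements(cl, toy$genome, "Fam")
  expect_length(res$elements, 1L)
  expect_equal(unname(res$log[c("kept", "dropped_short",
                                "dropped_missing_ltr")]),
               c(1L, 0L, 0L))
  el <- res$elements
  expect_equal(GenomicRanges::start(elementRanges(el)), toy$start)
  expect_equal(IRanges::start(leftLTR(el)), 1L)
  expect_equal(IRanges::end(leftLTR(el)), 350L)
  expect_equal(IRanges::end(rightLTR(el)), toy$element_len)

  # a single 400-bp LTR cluster: dropped by the span filter
  short <- frag_gr("chrT", 401, 800, "+", "Fam-LTR", "LTR")
  res2 <- callElements(mergeFragments(short), toy$genome, "Fam")
  expect_length(res2$elements, 0L)
  expect_equal(unname(res2$log[["dropped_short"]]), 1L)

  # internal+LTR with no 5' LTR: dropped when both LTRs required
  no5 <- frag_gr("chrT", c(401, 1301), c(1200, 1650), "+",
                 c("Fam-int", "Fam-LTR"), c("internal", "LTR"))
  res3 <- callElements(mergeFragments(no5), toy$genome, "Fam")
  expect_length(res3$elements, 0L)
  expect_equal(unname(res3$log[["dropped_missing_ltr"]]), 1L)
})

test_that("minus-strand elements are extracted in element orientation", {
  pbs <- "TGGACGTACGTACGTACG"
  plus <- toy_element_genome(pbs, seed = 77, strand = "+")
  minus <- toy_element_genome(pbs, seed = 77, strand = "-")
  ep <- callElements(mergeFragments(plus$annotations), plus$genome,
                     "Fam")$elements
  em <- callElements(mergeFragments(minus$annotations), minus$genome,
                     "Fam")$elements
  # identical oriented sequence regardless of genomic strand
  expect_equal(as.character(elementSeqs(ep)[[1]]),
               as.character(elementSeqs(em)[[1]]))
  expect_equal(as.character(GenomicRanges::strand(elementRanges(em))), "-")
  # PBS is found downstream of the oriented 5' LTR in both
  w <- unname(as.character(utrWindows(em)))
  expect_equal(substr(w, 4, 21), pbs)
})

test_that("tandem clusters split so each element keeps two flanking LTRs", {
  set.seed(12)
  ltr <- rand_dna(350); core <- rand_dna(800)
  one <- paste0(ltr, rand_dna(60), core, ltr)
  gseq <- paste0(rand_dna(200), one, rand_dna(100), one, rand_dna(200))
  genome <- Biostrings::DNAStringSet(c(chrT = gseq))
  L <- nchar(one)
  s1 <- 201L; s2 <- s1 + L + 100L
  ann <- frag_gr("chrT",
                 c(s1, s1 + 350L, s1 + L - 350L, s2, s2 + 350L, s2 + L - 350L),
                 c(s1 + 349L, s1 + L - 351L, s1 + L - 1L,
                   s2 + 349L, s2 + L - 351L, s2 + L - 1L),
                 "+", rep(c("Fam-LTR", "Fam-int", "Fam-LTR"), 2),
                 rep(c("LTR", "internal", "LTR"), 2))
  cl <- mergeFragments(ann, maxGap = 500)
  expect_length(cl, 1L) # gap 100 merges the tandem pair
  res <- callElements(cl, genome, "Fam")
  expect_length(res$elements, 2L)
  expect_equal(GenomicRanges::start(elementRanges(res$elements)),
               c(s1, s2))
})

test_that("clusters outside genome bounds raise a named error", {
  toy <- toy_element_genome("TGGACGTACGTACGTACG")
  bad <- frag_gr("chrT", c(1, 500, 100000), c(400, 99999, 100600), "+",
                 c("Fam-LTR", "Fam-int", "Fam-LTR"),
                 c("LTR", "internal", "LTR"))
  expect_error(
    callElements(GenomicRanges::GRangesList(bad), toy$genome, "Fam"),
    "outside the genome")
})
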