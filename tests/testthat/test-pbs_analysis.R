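test_that("perfectPBS is the reverse complement of the tRNA 3' 18-mer", {
  t20 <- "GGGTCGTTGGTTCGATTCCA"
  # independent oracle: Biostrings reverse complement of the last 18 nt
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(t20, 3, 20))))
  expect_equal(perfectPBS(t20), oracle)
  expect_equal(perfectPBS(t20), "TGGAATCGAACCAACGAC")
  # involution: revcomp of the perfect PBS is the tRNA 3' 18-mer
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(perfectPBS(t20)))), substr(t20, 3, 20))
  # every perfect PBS starts TGG (complement of the CCA tail)
  set.seed(3)
  for (i in 1:20)
    expect_match(perfectPBS(paste0(rand_dna(19), "CCA")), "^TGG")
  # RNA alphabet accepted
  expect_equal(perfectPBS(chartr("T", "U", t20)), perfectPBS(t20))
  expect_error(perfectPBS("ACCA"), "18")
  expect_error(perfectPBS(paste0(rand_dna(20), "CCG")), "CCA")
})

test_that("locatePBS recovers a planted perfect PBS at its offset", {
  trna <- rand_trna(21)
  pbs <- perfectPBS(trna)
  toy <- toy_element_genome(pbs, spacer = 3, seed = 31)
  el <- callElements(mergeFragments(toy$annotations), toy$genome,
                     "Fam")$elements
  calls <- locatePBS(el, setNames(Biostrings::DNAStringSet(trna), "Lys3-UUU"))
  expect_equal(calls$edit_distance, 0L)
  expect_equal(calls$offset, 3L)
  expect_equal(calls$pbs_gapped, pbs)
  expect_false(calls$unassigned)
  expect_false(calls$ambiguous_primer)
})

test_that("locatePBS reports substitutions of a mutated PBS", {
  trna <- rand_trna(22)
  pbs <- perfectPBS(trna)
  mut <- pbs
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(pbs, 5, 5))[1]
  substr(mut, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                 substr(pbs, 12, 12))[1]
  toy <- toy_element_genome(mut, spacer = 2, seed = 32)
  el <- callElements(mergeFragments(toy$annotations), toy$genome,
                     "Fam")$elements
  calls <- locatePBS(el, setNames(Biostrings::DNAStringSet(trna), "Lys3-UUU"))
  expect_equal(calls$edit_distance, 2L)
  expect_equal(calls$n_sub, 2L)
  expect_equal(sort(ervpbs:::parseAlignedPair(
    calls$ref_gapped, calls$pbs_gapped)$substitutions$pos), c(5L, 12L))
})

test_that("competitive primer assignment allows a primer switch", {
  t1 <- rand_trna(41); t2 <- rand_trna(42)
  trnas <- setNames(Biostrings::DNAStringSet(c(t1, t2)),
                    c("Lys3-UUU", "Lys1/2-CUU"))
  # element carries the perfect PBS of the *second* primer
  toy <- toy_element_genome(perfectPBS(t2), seed = 43)
  el <- callElements(mergeFragments(toy$annotations), toy$genome,
                     "Fam")$elements
  calls <- locatePBS(el, trnas)
  expect_equal(calls$primer_assigned, "Lys1/2-CUU")
  expect_equal(calls$edit_distance, 0L)
  expect_false(calls$ambiguous_primer)
})

test_that("variant tables count, sort and label P/C correctly", {
  mk_call <- function(id, obs, ref, d) data.frame(
    element_id = id, family = "Fam", primer_assigned = "Lys3-UUU",
    offset = 3L, edit_distance = d, pbs_gapped = obs, ref_gapped = ref,
    n_sub = d, n_ins = 0L, n_del = 0L, substitutions = "",
    insertions = "", deletions = "", ambiguous_primer = FALSE,
    unassigned = FALSE, stringsAsFactors = FALSE)
  ref <- "TGGAATCGAACCAACGAC"
  vA <- "TGGTATCGAACCAACGTC"; vB <- "TGGAATCGAACCAACGAA"
  calls <- rbind(
    do.call(rbind, lapply(1:6, function(i) mk_call(paste0("a", i), vA, ref, 2L))),
    do.call(rbind, lapply(1:3, function(i) mk_call(paste0("p", i), ref, ref, 0L))),
    mk_call("b1", vB, ref, 1L))
  tab <- tabulateVariants(calls)
  expect_equal(sum(tab$count), 10L)
  expect_equal(attr(tab, "total_elements"), 10L)
  expect_equal(tab$label[tab$pbs_gapped == vA], "C")
  expect_equal(tab$label[tab$pbs_gapped == ref], "P")
  expect_equal(tab$count[tab$pbs_gapped == ref], 3L)
  # counts invariant under input permutation
  set.seed(9)
  tab2 <- tabulateVariants(calls[sample(nrow(calls)), ])
  expect_identical(tab, tab2)
  # most common == perfect: single PC row
  calls3 <- do.call(rbind, lapply(1:4, function(i)
    mk_call(paste0("p", i), ref, ref, 0L)))
  expect_equal(tabulateVariants(calls3)$label, "PC")
  # perfect absent: appended with count 0, labelled P
  calls4 <- do.call(rbind, lapply(1:4, function(i)
    mk_call(paste0("a", i), vA, ref, 2L)))
  tab4 <- tabulateVariants(calls4)
  expect_equal(tab4$count[tab4$label == "P"], 0L)
  expect_equal(tab4$pbs_gapped[tab4$label == "P"], ref)
  # empty input: empty table with total 0
  tab5 <- tabulateVariants(calls[0, ])
  expect_equal(nrow(tab5), 0L)
  expect_equal(attr(tab5, "total_elements"), 0L)
})

test_that("mutation spectrum aggregates by element count with CpG context", {
  ref <- "TGGAACGGAACCAACGAC" # CG at positions 5-6? check: pos 5 'A'...
  # build a reference with a known CG dinucleotide at positions 6-7
  ref <- "TGGAACGGAACCAACGTC"
  stopifnot(substr(ref, 6, 7) == "CG")
  obs1 <- ref; substr(obs1, 6, 6) <- "T" # C>T at CpG position 6
  obs2 <- ref; substr(obs2, 3, 3) <- "A" # G>A at position 3
  tab <- data.frame(
    pbs_gapped = c(obs1, obs2), ref_gapped = c(ref, ref),
    count = c(7L, 2L), stringsAsFactors = FALSE)
  sp <- mutationSpectrum(tab)
  expect_equal(unname(sp$per_position[6]), 7L)
  expect_equal(unname(sp$per_position[3]), 2L)
  expect_equal(unname(sp$classes12[["C>T"]]), 7L)
  expect_equal(unname(sp$classes12[["G>A"]]), 2L)
  expect_equal(sp$editing_signature, 9L)
  expect_equal(sp$cpg_context, 7L)
  expect_equal(sp$total_substitutions, 9L)
  # strand-symmetric collapse: G>A counts into C>T class
  expect_equal(unname(sp$classes6[["C>T"]]), 9L)
  expect_equal(sum(sp$classes6), sp$total_substitutions)
})

test_that("tolerant/seed position annotation counts edits in and out", {
  ref <- "TGGAATCGAACCAACGAC"
  obs <- ref
  substr(obs, 3, 3) <- "A"; substr(obs, 11, 11) <- "G"
  tab <- data.frame(pbs_gapped = obs, ref_gapped = ref, count = 1L,
                    stringsAsFactors = FALSE)
  out <- annotatePositions(tab, tolerantPositions = 3)
  expect_equal(out$edits_tolerant, 1L)
  expect_equal(out$edits_nontolerant, 1L)
  # empty tolerant list: everything outside
  out2 <- annotatePositions(tab, tolerantPositions = integer(0))
  expect_equal(out2$edits_tolerant, 0L)
  expect_equal(out2$edits_nontolerant, 2L)
  # all positions tolerant: nothing outside
  out3 <- annotatePositions(tab, tolerantPositions = 1:18)
  expect_equal(out3$edits_nontolerant, 0L)
  # seed-complement region accounting (default PBS positions 12-17)
  obs4 <- ref; substr(obs4, 13, 13) <- "G"
  tab4 <- data.frame(pbs_gapped = obs4, ref_gapped = ref, count = 1L,
                     stringsAsFactors = FALSE)
  out4 <- annotatePositions(tab4, tolerantPositions = integer(0))
  expect_equal(out4$edits_seed, 1L)
  expect_equal(out4$edits_nonseed, 0L)
  expect_error(annotatePositions(tab, 19), "1..18")
})

test_that("reapplying reported edits reconstructs the observed PBS", {
  set.seed(55)
  trna <- rand_trna(66)
  ref <- perfectPBS(trna)
  for (i in 1:25) {
    obs <- ref
    # random 1-3 substitutions plus occasionally an interior deletion
    for (k in seq_len(sample(1:3, 1))) {
      p <- sample(1:18, 1)
      substr(obs, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (i %% 5 == 0) {
      p <- sample(3:16, 1)
      obs <- paste0(substr(obs, 1, p - 1), substr(obs, p + 1, nchar(obs)))
    }
    w <- paste0(rand_dna(3), obs, rand_dna(19))
    r <- fitAlign(ref, w, offsetRange = c(0, 10))
    expect_equal(ervpbs:::applyEditsToReference(ref, r),
                 gsub("-", "", r$obs_aln, fixed = TRUE))
  }
})
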