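# Shared fixture builders. All randomness is locally seeded.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent Levenshtein oracle: utils::adist with unit costs.
lev <- function(a, b) as.integer(utils::adist(a, b))

# Independent fit-alignment oracle: minimum Levenshtein distance from
# the query to any contiguous substring of the window (including the
# empty substring).
fit_oracle <- function(q, w) {
  n <- nchar(w)
  subs <- c("", unlist(lapply(seq_len(n), function(i)
    substring(w, i, i:n))))
  min(utils::adist(q, subs))
}

# A toy GRanges of repeat fragments.
frag_gr <- function(chrom, start, end, strand, name, role) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, repeat_name = name,
                         role = role, family = "Fam")
}

# One hand-built genome with a single plus-strand element:
#   300 bp pad | LTR(350) | spacer | PBS variant | tail(30) |
#   internal(800) | LTR(350 with given divergence edits) | 300 bp pad
# Returns the genome, annotations, and the layout.
toy_element_genome <- function(pbs, spacer = 3, ltr = NULL, right_ltr = NULL,
                               seed = 42, strand = "+") {
  set.seed(seed)
  if (is.null(ltr)) ltr <- rand_dna(350)
  if (is.null(right_ltr)) right_ltr <- ltr
  pad <- rand_dna(300)
  core <- rand_dna(800)
  el <- paste0(ltr, rand_dna(spacer), pbs, rand_dna(30), core, right_ltr)
  gseq <- paste0(pad, el, rand_dna(300))
  L <- nchar(el)
  ll <- nchar(ltr); rl <- nchar(right_ltr)
  s <- 301L
  ann <- if (strand == "+") {
    frag_gr("chrT", c(s, s + ll, s + L - rl),
            c(s + ll - 1L, s + L - rl - 1L, s + L - 1L),
            "+", c("Fam-LTR", "Fam-int", "Fam-LTR"),
            c("LTR", "internal", "LTR"))
  } else {
    gseq <- paste0(pad, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(el))), rand_dna(300))
    # element orientation reversed: the genomic-first LTR is the
    # element's 3' LTR
    frag_gr("chrT", c(s, s + rl, s + L - ll),
            c(s + rl - 1L, s + L - ll - 1L, s + L - 1L),
            "-", c("Fam-LTR", "Fam-int", "Fam-LTR"),
            c("LTR", "internal", "LTR"))
  }
  list(genome = Biostrings::DNAStringSet(c(chrT = gseq)),
       annotations = ann, element_len = L, start = s)
}

# A CCA-tailed random tRNA 3'-end.
rand_trna <- function(seed) {
  set.seed(seed)
  paste0(rand_dna(22), "CCA")
}

# Small standard simulation shared by several tests.
basic_sim_config <- function(seed = 11, n = 20, frag_prob = 0,
                             gap_range = c(100L, 400L)) {
  simulationConfig(
    seed = seed,
    families = list(list(
      name = "FamA", nElements = n, primer = "Lys3-UUU",
      variants = list(
        list(name = "perfect", edits = NULL, freq = 0.4),
        list(name = "v1",
             edits = data.frame(op = "sub", pos = 5, base = "A"),
             freq = 0.6)))),
    ltrLen = 300L, internalLen = 600L,
    fragmentation = list(prob = frag_prob, gapRange = gap_range))
}
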