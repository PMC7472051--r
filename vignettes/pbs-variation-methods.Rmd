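---
title: "Methods: PBS variation analysis of endogenous retroviruses"
author: "ervpbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBS variation analysis of endogenous retroviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervpbs)
```

## The biological question

LTR retroelements prime reverse transcription with the 3' end of a
host tRNA annealed to the primer binding site (PBS), the 18 nt lying a
few bases downstream of the 5' LTR. Because mature tRNAs carry a
post-transcriptional CCA tail, small RNAs from their 3' ends (3'-tRFs)
are perfectly complementary to any functional PBS but not to genomic
tDNA — they mark exactly the elements that can still replicate. A
perfect PBS therefore maximises both priming and silencing; PBS
variants that weaken tRF pairing while preserving priming should
accumulate in successful ERV families. This package measures that
signature in annotated genomes: which PBS variants exist per family,
how common each is relative to the perfect sequence, where the
mutations sit, whether they pattern with element age, and how they
score against the two functional tRF classes.

## Element assembly

RepeatMasker reports a full-length provirus as several fragments.
`mergeFragments()` clusters fragments on the same chromosome and
strand whose inter-fragment gap is at most `maxGap` (default 500
bases, measured as next start minus previous end on 0-based half-open
coordinates). Overlapping or nested fragments always merge; a running
maximum of fragment ends makes the rule well defined for nested
annotations. `callElements()` then keeps a cluster iff its merged span
is at least `minLen` (default 500 bases) **and** its first and last
LTR-role fragments flank at least one internal fragment. The length
filter is applied to the merged span, i.e. after merging; the
synthetic truth used in the tests is generated so that element
recovery does not depend on this ordering. Clusters containing only
LTR fragments are reported as solo LTRs — recombination products that
carry no PBS and are excluded from PBS analysis by construction.
Clusters with more than two LTR fragments (tandem insertions) are
split at LTR–LTR adjacencies that have internal sequence on both
sides, so each called element keeps exactly two flanking LTRs;
this prevents chimeric elements and is deterministic. Fragments of
other families inside a cluster's gaps are ignored rather than treated
as breakpoints — nested-insertion resolution is out of scope, and the
simplest rule is the documented one.

Coordinates are held in `GRanges`/`IRanges` (1-based inclusive, the
Bioconductor convention); BED input/output converts at the I/O
boundary and nowhere else, so off-by-one drift cannot accumulate.
Element sequences are stored oriented (reverse-complemented for
minus-strand elements) with LTR/internal sub-spans in element-local
coordinates; "left" LTR always means the 5' LTR of the transcript.

## PBS model and scoring

For a primer tRNA 3' end (≥ 18 nt, ending CCA), the perfect PBS is the
reverse complement of its 3'-terminal 18 nt, so it begins `TGG`. PBS
location uses fit (semi-global) alignment of this 18-mer inside a
5'-UTR window downstream of the 5' LTR: unit costs (match 0, mismatch
1, indel 1; `N` mismatches everything, including `N`), query fully
consumed, window overhangs free. The window is 40 nt and allowed start
offsets are 0–10 — deliberately wider than the biological 2–4 nt
LTR–PBS spacer, to tolerate imprecise LTR boundary annotations; both
are parameters. The alignment kernels are small Rcpp dynamic programs
with fully specified tie-breaking: smallest start offset first, then
(cost, indel-count) lexicographic minimisation so a substitution
representation is preferred over an equal-cost indel one, then a
traceback preferring diagonal over vertical over horizontal moves.
Their costs are verified in the test suite against independent
brute-force oracles (`utils::adist`, including a minimum over all
window substrings for the fit case) on thousands of random instances.

Primer assignment is competitive: every candidate primer of the family
is fit-aligned and the minimum-distance primer wins, which is what
detects primer switching (e.g. a Lys3-family element carrying the
perfect Lys1,2 PBS). Ties set an `ambiguous_primer` flag and resolve
by the configured primer order. Calls with distance above
`maxReportDistance` (default 8) are flagged `unassigned` — degenerate
PBSes are reported, not forced onto a primer.

`tabulateVariants()` counts unique variants keyed on the *gapped*
observed/reference pair, so indel variants remain distinct rows; rows
sort by descending count then lexicographically; the zero-distance row
is labelled `P`, the maximal-count row `C` (a single `PC` row when
they coincide), and a missing perfect row is appended with count 0.
`mutationSpectrum()` weights substitutions by element count (not
unique variant), reporting per-position counts over 1–18, the 12 raw
and 6 strand-symmetric classes, substitutions whose reference position
starts a CpG in the perfect PBS, and the G>A + C>T editing signature.
`annotatePositions()` counts each variant's edits inside versus
outside a user-supplied set of mismatch-tolerant positions (these are
data, not constants — no tRNA sequence or tolerant-position set is
hard-coded anywhere) and inside versus outside the seed-complement
region.

## tRF targeting rules

3'-tRFs are CCA-tailed suffixes of the tRNA: tRF3a (17–19 nt)
interferes with reverse-transcription priming; tRF3b (22 nt) silences
like a miRNA. `pairProfile()` slides the reverse complement of a tRF
along the element's 5'-UTR window and counts antiparallel
Watson–Crick mismatches (tRF position *i* pairs site position
*L − i + 1*); G:U wobble is not a match by default (a switch exists;
the choice is a convention, not a measurement). Verdicts: tRF3a is
susceptible only with at most `tRF3aMaxMismatch` (default 0) total
mismatches, irrespective of seed; tRF3b requires zero mismatches at
seed positions 2–7 and tolerates up to `tRF3bNonSeedCap` (default 3)
non-seed mismatches. The non-seed cap is a configurable guess — no
quantitative tolerance is established experimentally — and is flagged
as such. Indels and thermodynamics are not modelled in the duplex;
pairing is substitution-only by design.

Geometry note: since the tRNA 3' terminus pairs PBS position 1 (the
`TGG`/CCA anchor at the LTR-proximal end), a 22-nt tRF3b's extra 4 nt
pair *downstream* of PBS position 18, toward the internal region. The
pairing window is therefore the full 5'-UTR window, not the PBS alone.
The simulator plants those 4 downstream bases complementary to tRNA
positions 19–22, mirroring retroviral initiation complexes in which
the first 22 tRNA nucleotides pair.

## Element age and trees

Left–right LTR identity proxies age: LTRs are identical at integration
and diverge afterwards. The two LTRs are globally aligned at unit
costs; identity is `100 · matches / alignment length`, with gap
columns excluded from the numerator but included in the denominator
(an `ungapped` denominator is available by flag; the field uses both
conventions and neither is canonical). No substitution-model
correction is applied — raw identity is the quantity of interest, not
absolute time. `stratifyByAge()` bins elements by identity (half-open
bins, top bin closed at 100) and tabulates variants per bin; bin edges
are user-configurable with no default claim about what counts as
"young".

Trees are neighbor-joining on p-distances with pairwise deletion of
gap/`N` columns, bootstrapped by column resampling; supports are the
percentage of replicate trees containing each internal split of the
point tree. NJ was chosen over maximum-likelihood deliberately: the
purpose of the trees is to visualise whether `P` and `C` PBS variants
disperse across clades (arguing for repeated, independent origin of
the common variant rather than one expansion), NJ is exact on additive
matrices — which gives the module a sharp correctness oracle
(Robinson–Foulds 0 against the generating topology, tested on random
trees) — and bootstrap supports carry the uncertainty. Default 100
replicates keeps runs desk-scale and is configurable upward. The NJ
agglomeration itself is `ape::nj`; resampling, support counting and
Newick annotation (leaf suffixes `|P`, `|C`) are package code. All
bootstrap randomness flows from one seed and is bit-reproducible.

## The synthetic genome generator

`simulateERVGenome()` is first-class, tested code that defines the
study conditions for validation. It plants, per family:
LTR–spacer–PBS–internal–LTR elements in i.i.d. uniform background
sequence (≥ 1 kb apart), with a 2–4 nt spacer; PBS variants specified
as explicit edit lists with target frequencies; an optional exact
primer-switch fraction carrying the alternate primer's perfect PBS;
per-element LTR divergence (per-position substitution probability on
the 3' LTR, overridable per variant, so age–variant correlations can
be planted); internal-core divergence (default 0.01) for phylogenetic
signal; annotation fragmentation with configurable gap sizes on either
side of the 500-base merge limit; strand mixture; and decoys (solo
LTRs, internal-only fragments, sub-500-nt fragments). Variant and
switch fractions are allocated by largest-remainder rounding, so
planted counts are exact integers, and a truth table records every
planted item with an expected-survival flag.

Two generator invariants keep truth-recovery tests exact rather than
statistical: (i) primer tRNAs are random CCA-tailed 25-mers, redrawn
until every planted variant is strictly closer to its own primer's
perfect PBS than to any other's *and* each variant's distance to its
target equals its specified edit count (an edit that happened to
recreate the reference base would silently change the planted
distance); (ii) indel edits must sit at interior PBS positions 2–17,
because a terminal indel can be absorbed by the free end gaps of fit
alignment and would make the planted variant ambiguous. Real tRNA
libraries can be supplied for real runs; no tRNA sequence ships with
the package.

What the simulator does *not* emulate: repeat-rich background
composition, nested insertions of other families, sequencing error, or
any reverse-transcription chemistry. Passing the recovery tests
therefore demonstrates correctness of the pipeline's logic under
clean, fully specified conditions — not robustness to the full
messiness of a real RepeatMasker track, where boundary imprecision and
nested repeats will add noise the configurable windows and gap limits
are designed to absorb.

## Problem sizes and numerical choices

The validation suite runs three families × 200 elements (~3 Mb of
synthetic genome), 1000-instance alignment-oracle sweeps, 20 random
8-taxon additive matrices, and 100-replicate bootstraps — sizes chosen
so the whole suite completes in about a minute on one CPU while every
recovery check remains exact. Determinism contracts: identical seeds
give byte-identical simulator output and byte-identical pipeline
reports; all pipeline randomness (only the bootstrap) flows from one
seed argument. Degenerate inputs are defined, not accidental: empty
annotation files produce empty, well-formed reports; an element
shorter than LTR + window yields a truncated-window warning and a scan
of what exists; a sequence pair with no comparable columns is an error
in p-distance (and distance 0 only inside bootstrap replicates, where
an occasional all-excluded pair must not abort the run); negative NJ
branch lengths are clamped to zero.

## Known limitations

Identity-based dating saturates for old elements and ignores gene
conversion between LTRs. Fit alignment reports one optimal placement;
a genuinely repetitive 5'-UTR could admit co-optimal PBS placements,
resolved here by the documented deterministic tie-breaks. Variant
tables do not deduplicate identical elements at duplicated loci —
segmental duplications inflate counts by design, since no
deduplication rule is obviously right. The tRF3b non-seed cap and the
wobble switch are conventions awaiting experimental calibration.
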