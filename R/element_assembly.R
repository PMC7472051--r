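#' Merge fragmented repeat annotations into candidate element clusters
#'
#' RepeatMasker typically reports a full-length provirus as several
#' fragments (two LTR hits plus one or more internal hits, often
#' interrupted). Fragments on the same chromosome and strand whose gap
#' (next start minus previous end on 0-based half-open coordinates,
#' i.e. `start - end - 1` on the 1-based ranges held here) is at most
#' `maxGap` bases are merged into one cluster. Overlapping or nested
#' fragments (negative gap) always merge. Clusters never span
#' chromosomes or strands; fragment order and roles are preserved
#' within a cluster.
#'
#' Merging is idempotent and the clusters partition the input features.
#'
#' @param features a `GRanges` of one family's fragments, with `role`
#'   metadata (see [assignRoles()]).
#' @param maxGap maximum merge gap in bases (default 500).
#' @return A `GRangesList`, one element per cluster, in (chrom, strand,
#'   start) order.
#' @export
mergeFragments <- function(features, maxGap = 500L) {
  stopifnot(maxGap >= 0)
  if (length(features) == 0L)
    return(GenomicRanges::GRangesList())
  key <- paste(as.character(GenomicRanges::seqnames(features)),
               as.character(GenomicRanges::strand(features)))
  out <- list()
  for (k in sort(unique(key))) {
    gr <- features[key == k]
    o <- order(GenomicRanges::start(gr), GenomicRanges::end(gr))
    gr <- gr[o]
    if (length(gr) == 1L) { out[[length(out) + 1L]] <- gr; next }
    run_end <- cummax(GenomicRanges::end(gr))
    gap <- GenomicRanges::start(gr)[-1] - run_end[-length(gr)] - 1L
    brk <- which(gap > maxGap)
    cl <- cumsum(c(1L, as.integer(seq_along(gap) %in% brk)))
    for (g in split(seq_along(gr), cl))
      out[[length(out) + 1L]] <- gr[g]
  }
  # deterministic cluster order: chrom, start, strand
  ord <- order(vapply(out, function(g)
                 as.character(GenomicRanges::seqnames(g))[1], ""),
               vapply(out, function(g) min(GenomicRanges::start(g)), 0L),
               vapply(out, function(g)
                 as.character(GenomicRanges::strand(g))[1], ""))
  GenomicRanges::GRangesList(out[ord])
}

#' Report solo-LTR clusters
#'
#' Clusters consisting only of LTR-role fragments are solo LTRs (the
#' recombination product of an element's two LTRs); they carry no PBS
#' and are excluded from PBS analysis by construction. This reports
#' them as a useful by-product.
#'
#' @param clusters a `GRangesList` from [mergeFragments()].
#' @return A `GRanges` of all fragments in LTR-only clusters.
#' @export
soloLtrs <- function(clusters) {
  keep <- vapply(clusters, function(g) all(g$role == "LTR"), TRUE)
  if (!any(keep)) return(emptyRepeatGRanges())
  unlist(clusters[keep], use.names = FALSE)
}

# Split a cluster carrying more than two LTR fragments (tandem
# elements) at LTR-LTR adjacencies so each part keeps exactly two
# flanking LTRs. A split point is an adjacency between two LTR-role
# fragments with at least one internal fragment on each side.
splitTandem <- function(gr) {
  n <- length(gr)
  if (sum(gr$role == "LTR") <= 2L) return(list(gr))
  is_ltr <- gr$role == "LTR"
  is_int <- gr$role == "internal"
  cuts <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (is_ltr[i] && is_ltr[i + 1L] &&
        any(is_int[seq_len(i)]) && any(is_int[(i + 1L):n]))
      cuts <- c(cuts, i)
  }
  if (length(cuts) == 0L) return(list(gr))
  bounds <- c(0L, cuts, n)
  lapply(seq_len(length(bounds) - 1L), function(j)
    gr[(bounds[j] + 1L):bounds[j + 1L]])
}

#' Call full-length elements from merged clusters
#'
#' A cluster becomes a full-length element iff (i) its merged span is
#' at least `minLen` bases and (ii), when `requireBothLtrs`, its first
#' and last LTR-role fragments flank at least one internal fragment.
#' Clusters with more than two LTR fragments (tandem insertions) are
#' first split at LTR-LTR adjacencies so every element keeps exactly
#' two flanking LTRs. The element sequence is extracted from the genome
#' and reverse-complemented for minus-strand elements; LTR and internal
#' sub-spans are stored in element-local coordinates of that oriented
#' sequence. Element ids are deterministic:
#' `family:chrom:start-end:strand` (1-based inclusive span).
#'
#' @param clusters a `GRangesList` from [mergeFragments()].
#' @param genome a named `DNAStringSet` (or path to a FASTA file).
#' @param family family name stamped on the elements.
#' @param minLen minimum merged span in bases (default 500).
#' @param requireBothLtrs drop clusters missing a flanking LTR
#'   (default TRUE).
#' @return A list with `elements` (an [ElementSet-class]) and `log`
#'   (named integer vector of kept/dropped counts).
#' @export
callElements <- function(clusters, genome, family,
                         minLen = 500L, requireBothLtrs = TRUE) {
  if (is.character(genome)) genome <- readFasta(genome)
  parts <- list()
  for (cl in as.list(clusters)) parts <- c(parts, splitTandem(cl))
  n_in <- length(parts)
  kept <- list()
  n_short <- 0L; n_noltr <- 0L
  for (gr in parts) {
    span_start <- min(GenomicRanges::start(gr))
    span_end <- max(GenomicRanges::end(gr))
    if (span_end - span_start + 1L < minLen) { n_short <- n_short + 1L; next }
    ltr_idx <- which(gr$role == "LTR")
    int_idx <- which(gr$role == "internal")
    if (requireBothLtrs) {
      ok <- length(ltr_idx) >= 2L && length(int_idx) >= 1L &&
        any(int_idx > min(ltr_idx) & int_idx < max(ltr_idx))
      if (!ok) { n_noltr <- n_noltr + 1L; next }
    } else if (length(int_idx) == 0L) {
      n_noltr <- n_noltr + 1L; next
    }
    kept[[length(kept) + 1L]] <- gr
  }
  elements <- buildElementSet(kept, genome, family)
  log <- c(clusters = n_in, kept = length(kept),
           dropped_short = n_short, dropped_missing_ltr = n_noltr)
  list(elements = elements, log = log)
}

buildElementSet <- function(kept, genome, family) {
  n <- length(kept)
  if (n == 0L) {
    return(new("ElementSet",
      granges = GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                                       element_id = character(0),
                                       family = character(0)),
      seqs = Biostrings::DNAStringSet(),
      leftLTR = IRanges::IRanges(), rightLTR = IRanges::IRanges(),
      internal = IRanges::IRangesList()))
  }
  chroms <- character(n); starts <- integer(n); ends <- integer(n)
  strands <- character(n); ids <- character(n)
  seqs <- vector("list", n)
  lft <- IRanges::IRanges(rep(1L, n), rep(1L, n))
  rgt <- IRanges::IRanges(rep(1L, n), rep(1L, n))
  ints <- vector("list", n)
  for (k in seq_len(n)) {
    gr <- kept[[k]]
    chrom <- as.character(GenomicRanges::seqnames(gr))[1]
    strand <- as.character(GenomicRanges::strand(gr))[1]
    s <- min(GenomicRanges::start(gr)); e <- max(GenomicRanges::end(gr))
    if (!chrom %in% names(genome))
      stop("element on unknown sequence '", chrom, "'")
    if (s < 1L || e > length(genome[[chrom]]))
      stop("element ", family, ":", chrom, ":", s, "-", e,
           " extends outside the genome sequence")
    sq <- Biostrings::subseq(genome[[chrom]], s, e)
    if (strand == "-") sq <- Biostrings::reverseComplement(sq)
    # genomic fragment -> element-local oriented coordinates
    loc_start <- if (strand == "-") e - GenomicRanges::end(gr) + 1L
                 else GenomicRanges::start(gr) - s + 1L
    loc_end <- if (strand == "-") e - GenomicRanges::start(gr) + 1L
               else GenomicRanges::end(gr) - s + 1L
    ltr_idx <- which(gr$role == "LTR")
    int_idx <- which(gr$role == "internal")
    if (length(ltr_idx) >= 2L) {
      l5 <- ltr_idx[which.min(loc_start[ltr_idx])]
      l3 <- ltr_idx[which.max(loc_start[ltr_idx])]
    } else if (length(ltr_idx) == 1L) {
      l5 <- l3 <- ltr_idx[1]
    } else {
      l5 <- l3 <- NA_integer_
    }
    lft[k] <- if (is.na(l5)) IRanges::IRanges(1L, 0L)
              else IRanges::IRanges(loc_start[l5], loc_end[l5])
    rgt[k] <- if (is.na(l3)) IRanges::IRanges(e - s + 2L, e - s + 1L)
              else IRanges::IRanges(loc_start[l3], loc_end[l3])
    keep_int <- if (is.na(l5) || l5 == l3) int_idx
                else int_idx[loc_start[int_idx] >= loc_end[l5] &
                             loc_end[int_idx] <= loc_start[l3]]
    ir <- IRanges::IRanges(loc_start[keep_int], loc_end[keep_int])
    ints[[k]] <- ir[order(IRanges::start(ir))]
    chroms[k] <- chrom; starts[k] <- s; ends[k] <- e; strands[k] <- strand
    ids[k] <- sprintf("%s:%s:%d-%d:%s", family, chrom, s, e, strand)
    seqs[[k]] <- as.character(sq)
  }
  gr_out <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts, ends),
                                   strand = strands, element_id = ids,
                                   family = family)
  ss <- setNames(Biostrings::DNAStringSet(unlist(seqs)), ids)
  new("ElementSet", granges = gr_out, seqs = ss, leftLTR = lft,
      rightLTR = rgt, internal = IRanges::IRangesList(ints))
}

#' Combine ElementSets from several families
#'
#' @param ... `ElementSet` objects.
#' @return A single [ElementSet-class].
#' @export
combineElementSets <- function(...) {
  xs <- unname(Filter(function(x) length(x) > 0, list(...)))
  if (length(xs) == 0L) return(buildElementSet(list(), NULL, ""))
  grl <- lapply(xs, elementRanges)
  lv <- unique(unlist(lapply(grl, GenomeInfoDb::seqlevels)))
  grl <- lapply(grl, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  new("ElementSet",
      granges = do.call(c, grl),
      seqs = do.call(c, lapply(xs, elementSeqs)),
      leftLTR = do.call(c, lapply(xs, leftLTR)),
      rightLTR = do.call(c, lapply(xs, rightLTR)),
      internal = do.call(c, lapply(xs, internalRegions)))
}
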