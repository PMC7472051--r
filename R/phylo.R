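#' p-distance matrix with pairwise deletion
#'
#' Proportion of mismatching columns between each pair of equal-length
#' sequences; columns where either sequence has a gap (`-`) or `N` are
#' excluded pairwise from both numerator and denominator.
#'
#' @param seqs a named `DNAStringSet` or named character vector of
#'   equal-length (aligned or anchored) sequences.
#' @param zeroComparable what to do when a pair shares no comparable
#'   column: `"error"` (default) or `"zero"` (used during bootstrap
#'   resampling, where an occasional all-excluded replicate pair must
#'   not abort the run).
#' @return A symmetric numeric matrix with zero diagonal, dimnames set
#'   to the sequence names.
#' @export
pDistance <- function(seqs, zeroComparable = c("error", "zero")) {
  zeroComparable <- match.arg(zeroComparable)
  chr <- toupper(as.character(seqs))
  names(chr) <- names(seqs)
  if (length(unique(nchar(chr))) != 1L)
    stop("p-distance requires equal-length sequences")
  n <- length(chr)
  if (is.null(names(chr))) names(chr) <- as.character(seq_len(n))
  m <- do.call(rbind, strsplit(chr, "", fixed = TRUE))
  ok <- m != "-" & m != "N"
  d <- matrix(0, n, n, dimnames = list(names(chr), names(chr)))
  if (n >= 2) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L) {
      if (zeroComparable == "error")
        stop("no comparable columns between '", names(chr)[i], "' and '",
             names(chr)[j], "'")
      d[i, j] <- d[j, i] <- 0
    } else {
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on a distance matrix (via [ape::nj()];
#' exact on additive matrices, which is this module's correctness
#' oracle). Negative branch lengths are clamped to zero.
#'
#' @param D a symmetric distance matrix (taxa in dimnames).
#' @return An unrooted [ape::phylo] tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining requires at least 3 taxa")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrapped neighbor-joining tree
#'
#' Builds the point-estimate NJ tree from the p-distances of the input
#' sequences, then resamples alignment columns with replacement
#' `replicates` times, rebuilds an NJ tree per replicate, and reports
#' for each internal split of the point tree the percentage of
#' replicate trees containing it. Fixed seeds give bit-identical
#' supports.
#'
#' @param seqs named equal-length sequences (see [pDistance()]).
#' @param replicates bootstrap replicates (default 100).
#' @param seed RNG seed (default 1).
#' @return The point [ape::phylo] tree with `node.label` set to
#'   integer support percentages (root label empty).
#' @export
bootstrapTree <- function(seqs, replicates = 100L, seed = 1L) {
  stopifnot(replicates >= 1L)
  chr <- toupper(as.character(seqs))
  names(chr) <- names(seqs)
  if (is.null(names(chr))) names(chr) <- as.character(seq_along(chr))
  m <- do.call(rbind, strsplit(chr, "", fixed = TRUE))
  rownames(m) <- names(chr)
  point <- njTree(pDistance(setNames(chr, names(chr))))
  reps <- vector("list", replicates)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  L <- ncol(m)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rs <- setNames(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
                   names(chr))
    reps[[b]] <- njTree(pDistance(rs, zeroComparable = "zero"))
  }
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- as.integer(round(100 * counts / replicates))
  labs <- as.character(supp)
  labs[1] <- "" # root of the unrooted representation: trivial split
  point$node.label <- labs
  point
}

#' Write a Newick tree with PBS variant labels on leaves
#'
#' Leaf names are suffixed `|P` (perfect PBS) or `|C` (most common
#' PBS) according to the supplied labels; other leaves keep their bare
#' ids. Internal-node bootstrap supports, if present, are written as
#' node labels.
#'
#' @param tree an [ape::phylo] tree.
#' @param labels named character vector mapping leaf ids to
#'   `"P"`, `"C"`, `"PC"` or `"."`/`"other"`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeAnnotatedNewick <- function(tree, labels, path) {
  lab <- labels[tree$tip.label]
  suff <- ifelse(is.na(lab) | lab %in% c(".", "other", ""), "",
                 paste0("|", lab))
  tree$tip.label <- paste0(tree$tip.label, suff)
  writeNewick(tree, path)
}

#' Label elements P/C from a variant table
#'
#' @param calls PBS calls from [locatePBS()].
#' @param table a variant table from [tabulateVariants()].
#' @return A named character vector (element id -> `P`, `C`, `PC` or
#'   `.`).
#' @export
variantLeafLabels <- function(calls, table) {
  key <- paste(calls$pbs_gapped, calls$ref_gapped)
  tkey <- paste(table$pbs_gapped, table$ref_gapped)
  lab <- table$label[match(key, tkey)]
  lab[is.na(lab)] <- "."
  setNames(lab, calls$element_id)
}
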