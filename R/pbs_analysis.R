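#' Build the perfect PBS from a primer tRNA 3' end
#'
#' The primer binding site complementary to a tRNA primer is the
#' reverse complement of the 3'-terminal 18 nt of the mature tRNA
#' (which carries the post-transcriptional CCA tail). The returned
#' 18-mer therefore always begins `TGG`. RNA input (`U`) is accepted
#' and mapped to `T`.
#'
#' @param trna a tRNA 3'-end sequence (character, `DNAString`, or a
#'   named character/`DNAStringSet` of several tRNAs), at least 18 nt
#'   and ending in `CCA`.
#' @return The 18-nt perfect PBS as a character scalar, or a named
#'   character vector for multi-sequence input.
#' @examples
#' perfectPBS("GGGTCGTTGGTTCGATTCCA")
#' @export
perfectPBS <- function(trna) {
  if (is(trna, "DNAStringSet") || (is.character(trna) && length(trna) > 1L))
    return(vapply(setNames(as.character(trna), names(trna)), perfectPBS, ""))
  s <- chartr("Uu", "Tt", toupper(as.character(trna)))
  if (nchar(s) < 18L)
    stop("tRNA 3'-end must be at least 18 nt (got ", nchar(s), ")")
  if (!endsWith(s, "CCA"))
    stop("tRNA 3'-end must end in the post-transcriptional CCA tail")
  tail18 <- substr(s, nchar(s) - 17L, nchar(s))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(tail18)))
}

#' Locate and score the PBS of each element
#'
#' For every element, the 5'-UTR window downstream of the 5' LTR is
#' scanned with the perfect PBS of each candidate primer by fit
#' alignment (query fully consumed, free end gaps on the window, unit
#' costs). The call reports the primer and placement minimising the
#' edit distance. Ties between primers set `ambiguous_primer` and are
#' broken by primer order in `trnas`; ties in placement are broken by
#' smallest offset. Calls with distance above `maxReportDistance` are
#' flagged `unassigned` (degenerate PBS) but still reported against
#' their best primer.
#'
#' @param elements an [ElementSet-class].
#' @param trnas named `DNAStringSet` (or named character) of candidate
#'   primer tRNA 3'-ends, in priority order; perfect PBSes are derived
#'   with [perfectPBS()].
#' @param windowLen nt of 5'-UTR scanned (default 40).
#' @param offsetRange allowed PBS start offsets downstream of the LTR
#'   end, 0-based (default `c(0, 10)`, generously covering the 2-4 nt
#'   spacer while tolerating imprecise LTR boundaries).
#' @param maxReportDistance distance cap for primer assignment
#'   (default 8).
#' @return A data.frame of PBS calls, one row per element: `element_id`,
#'   `family`, `primer_assigned`, `offset`, `edit_distance`,
#'   `pbs_gapped` (observed PBS aligned to the perfect PBS, gaps `-`),
#'   `ref_gapped`, `n_sub`/`n_ins`/`n_del`, encoded edit strings, and
#'   the `ambiguous_primer`/`unassigned` flags.
#' @export
locatePBS <- function(elements, trnas, windowLen = 40L,
                      offsetRange = c(0L, 10L), maxReportDistance = 8L) {
  stopifnot(is(elements, "ElementSet"), length(trnas) >= 1L,
            windowLen >= 18L, offsetRange[1] >= 0L)
  pbs_ref <- perfectPBS(trnas)
  wins <- utrWindows(elements, windowLen)
  fams <- elementRanges(elements)$family
  n <- length(elements)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    w <- as.character(wins[[k]])
    best <- NULL; best_primer <- NA_character_; ambig <- FALSE
    for (p in names(pbs_ref)) {
      r <- fitAlign(pbs_ref[[p]], w, offsetRange)
      if (is.null(best) || r$cost < best$cost) {
        best <- r; best_primer <- p; ambig <- FALSE
      } else if (r$cost == best$cost && p != best_primer) {
        ambig <- TRUE
      }
    }
    ed <- encodeEdits(best)
    rows[[k]] <- data.frame(
      element_id = names(elements)[k],
      family = fams[k],
      primer_assigned = best_primer,
      offset = best$offset,
      edit_distance = best$cost,
      pbs_gapped = best$obs_aln,
      ref_gapped = best$ref_aln,
      n_sub = nrow(best$substitutions),
      n_ins = nrow(best$insertions),
      n_del = nrow(best$deletions),
      substitutions = ed$substitutions,
      insertions = ed$insertions,
      deletions = ed$deletions,
      ambiguous_primer = ambig,
      unassigned = best$cost > maxReportDistance,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Tabulate unique PBS variants of one family and primer
#'
#' Counts how many elements carry each unique PBS variant (keyed on the
#' gapped representation relative to the perfect PBS, so indel variants
#' remain distinct), sorted by descending count then lexicographically.
#' The zero-distance row is labelled `P` (perfect); the maximal-count
#' row is labelled `C` (common); a row that is both is labelled `PC`;
#' all others `.`. If no element carries the perfect PBS, a `P` row
#' with count 0 is appended. Unassigned (degenerate) calls are
#' excluded.
#'
#' @param calls a data.frame from [locatePBS()].
#' @param family,primer select one family and assigned primer; `NULL`
#'   (default) uses the calls as given.
#' @param perfect the perfect PBS sequence for the `P` row; derived
#'   from the calls' zero-distance row or `ref_gapped` if omitted.
#' @return A data.frame with columns `family`, `primer`, `pbs_gapped`,
#'   `ref_gapped`, `count`, `edit_distance`, `label`, plus attribute
#'   `total_elements`.
#' @export
tabulateVariants <- function(calls, family = NULL, primer = NULL,
                             perfect = NULL) {
  if (!is.null(family)) calls <- calls[calls$family == family, , drop = FALSE]
  if (!is.null(primer))
    calls <- calls[calls$primer_assigned == primer, , drop = FALSE]
  calls <- calls[!calls$unassigned, , drop = FALSE]
  fam <- if (!is.null(family)) family else
    if (nrow(calls)) calls$family[1] else NA_character_
  prm <- if (!is.null(primer)) primer else
    if (nrow(calls)) calls$primer_assigned[1] else NA_character_
  if (nrow(calls) == 0L) {
    out <- data.frame(family = character(0), primer = character(0),
                      pbs_gapped = character(0), ref_gapped = character(0),
                      count = integer(0), edit_distance = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
    attr(out, "total_elements") <- 0L
    return(out)
  }
  key <- paste(calls$pbs_gapped, calls$ref_gapped, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(agg) <- c("key", "count")
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  agg$pbs_gapped <- vapply(parts, `[`, "", 1L)
  agg$ref_gapped <- vapply(parts, `[`, "", 2L)
  agg$edit_distance <-
    calls$edit_distance[match(agg$key, key)]
  agg <- agg[order(-agg$count, agg$pbs_gapped, agg$ref_gapped), , drop = FALSE]
  if (is.null(perfect))
    perfect <- gsub("-", "", agg$ref_gapped[1], fixed = TRUE)
  if (!any(agg$edit_distance == 0L)) {
    agg <- rbind(agg, data.frame(key = "", count = 0L,
                                 pbs_gapped = perfect, ref_gapped = perfect,
                                 edit_distance = 0L,
                                 stringsAsFactors = FALSE))
  }
  label <- rep(".", nrow(agg))
  label[which.max(agg$count)] <- "C"
  p_row <- which(agg$edit_distance == 0L)
  label[p_row] <- ifelse(label[p_row] == "C", "PC", "P")
  out <- data.frame(family = fam, primer = prm,
                    pbs_gapped = agg$pbs_gapped, ref_gapped = agg$ref_gapped,
                    count = agg$count, edit_distance = agg$edit_distance,
                    label = label, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_elements") <- sum(out$count)
  out
}

#' Mutation spectrum of PBS substitutions
#'
#' Aggregates substitutions relative to the perfect PBS, weighted by
#' element count (every element contributes, not every unique
#' variant). Reports the per-position histogram over PBS positions
#' 1..18, the 12 raw substitution classes, the 6 strand-symmetric
#' classes (keyed by the pyrimidine of the reference pair), the number
#' of substitutions whose reference position starts a CpG dinucleotide
#' in the perfect PBS, and the cytidine-deamination / editing signature
#' count (G>A plus C>T).
#'
#' @param x PBS calls from [locatePBS()] (weight 1 per row) or a
#'   variant table from [tabulateVariants()] (weighted by `count`).
#' @return An object of class `MutationSpectrum`: a list with
#'   `per_position`, `classes12`, `classes6`, `cpg_context`,
#'   `editing_signature` and `total_substitutions`.
#' @export
mutationSpectrum <- function(x) {
  weights <- if ("count" %in% names(x)) x$count else rep(1L, nrow(x))
  per_pos <- setNames(integer(18L), as.character(1:18))
  from <- c("A", "C", "G", "T")
  classes12 <- setNames(integer(12L),
    unlist(lapply(from, function(f)
      paste0(f, ">", setdiff(from, f)))))
  cpg <- 0L
  if (nrow(x)) for (k in seq_len(nrow(x))) {
    w <- weights[k]
    if (w == 0L) next
    parsed <- parseAlignedPair(x$ref_gapped[k], x$pbs_gapped[k])
    subs <- parsed$substitutions
    subs <- subs[subs$from %in% from & subs$to %in% from, , drop = FALSE]
    if (nrow(subs) == 0L) next
    ref <- gsub("-", "", x$ref_gapped[k], fixed = TRUE)
    for (j in seq_len(nrow(subs))) {
      p <- subs$pos[j]
      per_pos[p] <- per_pos[p] + w
      cls <- paste0(subs$from[j], ">", subs$to[j])
      classes12[cls] <- classes12[cls] + w
      if (p < nchar(ref) && substr(ref, p, p + 1L) == "CG")
        cpg <- cpg + w
    }
  }
  pair <- c("A>C" = "T>G", "A>G" = "T>C", "A>T" = "T>A",
            "G>A" = "C>T", "G>C" = "C>G", "G>T" = "C>A")
  classes6 <- classes12[c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")]
  for (nm in names(pair)) classes6[pair[[nm]]] <-
    classes6[pair[[nm]]] + classes12[[nm]]
  structure(list(
    per_position = per_pos,
    classes12 = classes12,
    classes6 = classes6,
    cpg_context = cpg,
    editing_signature = unname(classes12["G>A"] + classes12["C>T"]),
    total_substitutions = sum(classes12)
  ), class = "MutationSpectrum")
}

#' @export
print.MutationSpectrum <- function(x, ...) {
  cat("PBS mutation spectrum:", x$total_substitutions, "substitutions\n")
  cat("  editing signature (G>A + C>T):", x$editing_signature, "\n")
  cat("  CpG-context:", x$cpg_context, "\n")
  nz <- x$classes12[x$classes12 > 0]
  if (length(nz))
    cat("  classes:", paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Annotate variant rows with tolerant-position and seed-region counts
#'
#' For each variant row, counts its edits (substitutions and indels,
#' at their reference positions) inside versus outside a user-supplied
#' set of mismatch-tolerant PBS positions (e.g. positions found
#' tolerant in retroviral PBS-editing escape studies), and inside
#' versus outside the seed-complement region of the PBS (the PBS
#' positions paired by tRF seed nucleotides 2-7; positions 12-17 for
#' an 18-nt 3'-tRF).
#'
#' @param table a variant table from [tabulateVariants()].
#' @param tolerantPositions integer vector of PBS positions in 1..18.
#' @param seedRegion PBS positions complementary to the tRF seed
#'   (default 12:17).
#' @return The table with columns `edits_tolerant`, `edits_nontolerant`,
#'   `edits_seed`, `edits_nonseed` appended.
#' @export
annotatePositions <- function(table, tolerantPositions,
                              seedRegion = 12:17) {
  tolerantPositions <- as.integer(tolerantPositions)
  if (length(tolerantPositions) &&
      (any(tolerantPositions < 1L) || any(tolerantPositions > 18L)))
    stop("tolerant positions must lie in 1..18")
  n <- nrow(table)
  et <- en <- es <- eo <- integer(n)
  for (k in seq_len(n)) {
    parsed <- parseAlignedPair(table$ref_gapped[k], table$pbs_gapped[k])
    pos <- c(parsed$substitutions$pos, parsed$deletions$pos,
             pmax(parsed$insertions$pos, 1L))
    et[k] <- sum(pos %in% tolerantPositions)
    en[k] <- length(pos) - et[k]
    es[k] <- sum(pos %in% seedRegion)
    eo[k] <- length(pos) - es[k]
  }
  table$edits_tolerant <- et
  table$edits_nontolerant <- en
  table$edits_seed <- es
  table$edits_nonseed <- eo
  table
}
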