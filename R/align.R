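#' Unit-cost global alignment
#'
#' Needleman-Wunsch with match 0, mismatch 1, gap 1 (`N` mismatches
#' everything, including `N`). Traceback is deterministic: at equal
#' cost the diagonal move is preferred, then the vertical (gap in `b`),
#' then the horizontal (gap in `a`). The cost equals the Levenshtein
#' edit distance between the two sequences.
#'
#' @param a,b DNA strings (character scalars over A/C/G/T/N).
#' @return A list with `cost`, the aligned strings `aln_a`/`aln_b`
#'   (gaps as `-`), `aligned_length`, `matches` (identical non-`N`
#'   paired columns) and `gap_columns`.
#' @examples
#' globalAlign("ACGT", "ACTT")$matches  # 3
#' @export
globalAlign <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("global alignment of an empty sequence")
  cpp_global_align(a, b)
}

#' Fit ("semi-global") alignment of a short query inside a window
#'
#' Aligns the full query against a window with free end gaps on the
#' window (the query must be entirely consumed, window bases outside
#' the placement are not penalised). Unit costs as in [globalAlign()].
#' The placement start may be restricted to an offset range (0-based
#' from the window start). Ties are resolved deterministically:
#' smallest start offset, then smallest end, then a traceback
#' preferring substitution over indel and deletion over insertion.
#'
#' @param query query string (e.g. an 18-nt perfect PBS).
#' @param window window string to scan.
#' @param offsetRange integer length-2 vector of allowed 0-based start
#'   offsets (default: anywhere in the window).
#' @return A list with `cost` (edit distance), `offset` (0-based start
#'   of the placement), `end_offset`, the gapped `ref_aln` (query) and
#'   `obs_aln` (window segment), and parsed edit lists `substitutions`
#'   (data.frame pos/from/to; positions 1..nchar(query) on the query),
#'   `insertions` (data.frame pos/base; `pos` is the query position
#'   after which the base is inserted, 0 for a leading insertion) and
#'   `deletions` (data.frame pos/base).
#' @examples
#' fitAlign("TGGA", "TTGGA")$offset  # 1
#' @export
fitAlign <- function(query, window,
                     offsetRange = c(0L, nchar(window) - 1L)) {
  query <- toupper(as.character(query))
  window <- toupper(as.character(window))
  res <- cpp_fit_align(query, window,
                       as.integer(offsetRange[1]), as.integer(offsetRange[2]))
  c(res, parseAlignedPair(res$ref_aln, res$obs_aln))
}

# Decompose an aligned (reference, observed) pair into substitution,
# insertion and deletion lists. Reference positions are 1-based over
# the ungapped reference.
parseAlignedPair <- function(ref, obs) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  o <- strsplit(obs, "", fixed = TRUE)[[1]]
  rpos <- cumsum(r != "-")
  both <- r != "-" & o != "-"
  mism <- both & (r != o | r == "N" | o == "N")
  subs <- data.frame(pos = rpos[mism], from = r[mism], to = o[mism],
                     stringsAsFactors = FALSE)
  ins_i <- which(r == "-")
  insertions <- data.frame(pos = rpos[ins_i], base = o[ins_i],
                           stringsAsFactors = FALSE)
  del_i <- which(o == "-" & r != "-")
  deletions <- data.frame(pos = rpos[del_i], base = r[del_i],
                          stringsAsFactors = FALSE)
  list(substitutions = subs, insertions = insertions, deletions = deletions)
}

# Compact string encoding of edit lists, e.g. "5:C>T;12:G>A",
# "3:+A" (insertion after ref pos 3), "7:-G" (deletion of ref pos 7).
encodeEdits <- function(parsed) {
  s <- sprintf("%d:%s>%s", parsed$substitutions$pos,
               parsed$substitutions$from, parsed$substitutions$to)
  i <- sprintf("%d:+%s", parsed$insertions$pos, parsed$insertions$base)
  d <- sprintf("%d:-%s", parsed$deletions$pos, parsed$deletions$base)
  list(substitutions = paste(s, collapse = ";"),
       insertions = paste(i, collapse = ";"),
       deletions = paste(d, collapse = ";"))
}

# Inverse of the gapped representation: apply the reported edits to the
# ungapped reference and return the observed sequence. Used by tests to
# check call self-consistency.
applyEditsToReference <- function(ref_ungapped, parsed) {
  chars <- strsplit(ref_ungapped, "", fixed = TRUE)[[1]]
  out <- vector("list", length(chars) + 1L)
  for (k in seq_along(chars)) out[[k + 1L]] <- chars[k]
  if (nrow(parsed$substitutions))
    for (k in seq_len(nrow(parsed$substitutions)))
      out[[parsed$substitutions$pos[k] + 1L]] <- parsed$substitutions$to[k]
  if (nrow(parsed$deletions))
    for (k in seq_len(nrow(parsed$deletions)))
      out[[parsed$deletions$pos[k] + 1L]] <- character(0)
  if (nrow(parsed$insertions))
    for (k in seq_len(nrow(parsed$insertions)))
      out[[parsed$insertions$pos[k] + 1L]] <-
        c(out[[parsed$insertions$pos[k] + 1L]], parsed$insertions$base[k])
  paste(unlist(out), collapse = "")
}
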