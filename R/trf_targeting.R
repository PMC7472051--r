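#' Derive 3'-tRFs from a primer tRNA
#'
#' 3'-tRFs are suffixes of the mature tRNA carrying the CCA tail and
#' come in two functional size classes: tRF3a (17-19 nt), which blocks
#' reverse-transcription priming, and tRF3b (22 nt), which silences
#' like a miRNA via seed pairing. Lengths outside these classes are an
#' error.
#'
#' @param trna a tRNA 3'-end sequence (character or `DNAString`),
#'   ending in CCA.
#' @param lengths tRF lengths to derive (default `c(18, 22)`).
#' @param name tRNA name used to label the fragments.
#' @return A data.frame with columns `name`, `trf_class`, `length`,
#'   `seq` (5'->3', ends CCA).
#' @examples
#' makeTRFs("GGGTCGTTGGTTCGATTCCA", c(18, 19))
#' @export
makeTRFs <- function(trna, lengths = c(18L, 22L), name = "tRF") {
  s <- chartr("Uu", "Tt", toupper(as.character(trna)))
  lengths <- as.integer(lengths)
  if (any(!lengths %in% c(17L, 18L, 19L, 22L)))
    stop("tRF lengths must be 17-19 (tRF3a) or 22 (tRF3b); got ",
         paste(setdiff(lengths, c(17:19, 22)), collapse = ", "))
  if (any(lengths > nchar(s)))
    stop("tRF length exceeds the tRNA 3'-end length")
  data.frame(
    name = sprintf("%s-%d", name, lengths),
    trf_class = ifelse(lengths == 22L, "tRF3b", "tRF3a"),
    length = lengths,
    seq = vapply(lengths, function(L)
      substr(s, nchar(s) - L + 1L, nchar(s)), ""),
    stringsAsFactors = FALSE)
}

#' Complementarity profile of a tRF along a 5'-UTR window
#'
#' Slides the reverse complement of the tRF along the target window
#' and, for every placement, counts antiparallel Watson-Crick
#' mismatches (tRF position `i` pairs target position
#' `site_end - i + 1`). G:U wobble is not counted as a match unless
#' `wobble = TRUE`. The best placement (fewest mismatches; leftmost on
#' ties) is returned together with the per-position match vector in
#' tRF coordinates (position 1 = tRF 5' end).
#'
#' @param trfSeq tRF sequence, 5'->3' (character).
#' @param utr the element's 5'-UTR window (character or `DNAString`).
#' @param seedRange tRF seed positions (default 2:7, counted from the
#'   tRF 5' end, miRNA convention).
#' @param wobble count G:U pairs as matches (default FALSE).
#' @return A list with `found`, `site_start`/`site_end` (1-based in
#'   the window), `total_mismatches`, `seed_mismatches` and
#'   `match` (logical vector in tRF coordinates). When the window is
#'   shorter than the tRF, `found` is FALSE (no-site result).
#' @export
pairProfile <- function(trfSeq, utr, seedRange = 2:7, wobble = FALSE) {
  trf <- chartr("Uu", "Tt", toupper(as.character(trfSeq)))
  utr <- toupper(as.character(utr))
  L <- nchar(trf); n <- nchar(utr)
  if (n < L)
    return(list(found = FALSE, site_start = NA_integer_,
                site_end = NA_integer_, total_mismatches = NA_integer_,
                seed_mismatches = NA_integer_, match = logical(0)))
  site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(trf)))
  sv <- strsplit(site, "", fixed = TRUE)[[1]]
  uv <- strsplit(utr, "", fixed = TRUE)[[1]]
  trf_v <- strsplit(trf, "", fixed = TRUE)[[1]]
  best_mm <- Inf; best_i <- NA_integer_; best_match <- NULL
  for (i in seq_len(n - L + 1L)) {
    tgt <- uv[i:(i + L - 1L)]
    m <- sv == tgt & sv != "N" & tgt != "N"
    if (wobble) {
      # G:U wobble between the tRF base and the target base
      # (target in DNA: U == T)
      tb <- rev(trf_v) # tRF base pairing target column j is trf[L-j+1]
      m <- m | (tb == "G" & tgt == "T") | (tb == "T" & tgt == "G")
    }
    mm <- sum(!m)
    if (mm < best_mm) { best_mm <- mm; best_i <- i; best_match <- m }
  }
  # convert target-column matches to tRF coordinates (antiparallel)
  match_trf <- rev(best_match)
  list(found = TRUE,
       site_start = best_i,
       site_end = best_i + L - 1L,
       total_mismatches = as.integer(best_mm),
       seed_mismatches = as.integer(sum(!match_trf[seedRange])),
       match = match_trf)
}

#' Score susceptibility of an element site to a tRF
#'
#' tRF3a fragments abrogate reverse-transcription priming and are
#' highly sensitive to any mismatch irrespective of the seed: the
#' default verdict is susceptible only at `total_mismatches <=
#' tRF3aMaxMismatch` (0). tRF3b fragments act like miRNAs: a perfect
#' seed pairing is required, while non-seed mismatches are tolerated
#' up to a configurable cap (default 3; the cap is a configurable
#' guess, not an experimentally derived constant).
#'
#' @param profile a profile from [pairProfile()].
#' @param trfClass `"tRF3a"` or `"tRF3b"`.
#' @param tRF3aMaxMismatch mismatch cap for tRF3a (default 0).
#' @param tRF3bNonSeedCap non-seed mismatch cap for tRF3b (default 3).
#' @return A list with `verdict` (`"susceptible"` or `"evading"`),
#'   `trf_class`, `total_mismatches`, `seed_mismatches`,
#'   `site_start`, `site_end`.
#' @export
scoreSusceptibility <- function(profile, trfClass,
                                tRF3aMaxMismatch = 0L,
                                tRF3bNonSeedCap = 3L) {
  stopifnot(trfClass %in% c("tRF3a", "tRF3b"))
  if (!isTRUE(profile$found))
    return(list(verdict = "evading", trf_class = trfClass,
                total_mismatches = NA_integer_,
                seed_mismatches = NA_integer_,
                site_start = NA_integer_, site_end = NA_integer_))
  verdict <- if (trfClass == "tRF3a") {
    if (profile$total_mismatches <= tRF3aMaxMismatch) "susceptible"
    else "evading"
  } else {
    nonseed <- profile$total_mismatches - profile$seed_mismatches
    if (profile$seed_mismatches == 0L && nonseed <= tRF3bNonSeedCap)
      "susceptible" else "evading"
  }
  list(verdict = verdict, trf_class = trfClass,
       total_mismatches = profile$total_mismatches,
       seed_mismatches = profile$seed_mismatches,
       site_start = profile$site_start, site_end = profile$site_end)
}

#' Score every element against the tRFs of its candidate primers
#'
#' Convenience wrapper for the pipeline: derives tRFs of the requested
#' lengths from each primer tRNA, scans each element's 5'-UTR window
#' and scores susceptibility.
#'
#' @param elements an [ElementSet-class].
#' @param trnas named `DNAStringSet`/character of primer tRNA 3'-ends.
#' @param lengths tRF lengths (default `c(18, 22)`).
#' @param windowLen 5'-UTR window length scanned (default 40).
#' @param ... passed to [scoreSusceptibility()].
#' @return A data.frame of susceptibility calls, one row per
#'   element x tRF.
#' @export
scoreElementTRFs <- function(elements, trnas, lengths = c(18L, 22L),
                             windowLen = 40L, ...) {
  wins <- utrWindows(elements, windowLen)
  rows <- list()
  for (p in names(trnas)) {
    trfs <- makeTRFs(as.character(trnas[[p]]), lengths, name = p)
    for (t in seq_len(nrow(trfs))) {
      for (k in seq_along(wins)) {
        prof <- pairProfile(trfs$seq[t], as.character(wins[[k]]))
        sc <- scoreSusceptibility(prof, trfs$trf_class[t], ...)
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = names(wins)[k],
          trf = trfs$name[t], trf_class = trfs$trf_class[t],
          site_start = sc$site_start, site_end = sc$site_end,
          total_mismatches = sc$total_mismatches,
          seed_mismatches = sc$seed_mismatches,
          verdict = sc$verdict, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
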