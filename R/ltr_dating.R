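#' LTR-LTR percent identity as an element age proxy
#'
#' The two LTRs of a provirus are identical at integration time, so
#' their divergence proxies element age: young elements have high
#' left-right LTR identity. Each element's LTR pair is globally
#' aligned with unit costs ([globalAlign()]) and identity is
#' `100 * matches / aligned_length`. Gap columns are excluded from the
#' match numerator but included in the aligned length by default; set
#' `denominator = "ungapped"` to exclude them from the denominator
#' too.
#'
#' @param elements an [ElementSet-class].
#' @param denominator `"aligned"` (default, alignment-length
#'   convention) or `"ungapped"`.
#' @return A data.frame with columns `element_id`, `aligned_length`,
#'   `matches`, `gap_columns`, `percent_identity`.
#' @export
ltrIdentity <- function(elements, denominator = c("aligned", "ungapped")) {
  denominator <- match.arg(denominator)
  stopifnot(is(elements, "ElementSet"))
  n <- length(elements)
  out <- data.frame(element_id = names(elements),
                    aligned_length = integer(n), matches = integer(n),
                    gap_columns = integer(n),
                    percent_identity = numeric(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    lr <- leftLTR(elements)[k]; rr <- rightLTR(elements)[k]
    if (IRanges::width(lr) == 0L || IRanges::width(rr) == 0L)
      stop("element ", names(elements)[k], " is missing an LTR sub-span")
    a <- as.character(Biostrings::subseq(elementSeqs(elements)[[k]],
                                         IRanges::start(lr),
                                         IRanges::end(lr)))
    b <- as.character(Biostrings::subseq(elementSeqs(elements)[[k]],
                                         IRanges::start(rr),
                                         IRanges::end(rr)))
    al <- globalAlign(a, b)
    den <- if (denominator == "aligned") al$aligned_length
           else al$aligned_length - al$gap_columns
    out$aligned_length[k] <- al$aligned_length
    out$matches[k] <- al$matches
    out$gap_columns[k] <- al$gap_columns
    out$percent_identity[k] <- if (den > 0) 100 * al$matches / den else 0
  }
  out
}

#' Stratify PBS variant frequencies by element age
#'
#' Bins elements by LTR-LTR percent identity and tabulates the PBS
#' variants within each bin, to ask whether particular variants (e.g.
#' the family's most common PBS) are enriched in younger, high-identity
#' copies. Bin edges are half-open `[lo, hi)`; the last bin is closed
#' at its upper edge so that 100% identity is included.
#'
#' @param calls PBS calls from [locatePBS()].
#' @param identities a data.frame from [ltrIdentity()].
#' @param bins ascending numeric bin edges covering `[0, 100]`
#'   (default `c(0, 90, 95, 100)`).
#' @return A data.frame of per-bin variant rows (columns of
#'   [tabulateVariants()] plus `bin`, `bin_lo`, `bin_hi`,
#'   `n_elements`).
#' @export
stratifyByAge <- function(calls, identities, bins = c(0, 90, 95, 100)) {
  bins <- as.numeric(bins)
  if (is.unsorted(bins, strictly = TRUE))
    stop("bins must be strictly increasing edges (overlapping or ",
         "degenerate bins are not allowed)")
  if (bins[1] > 0 || bins[length(bins)] < 100)
    stop("bins must cover [0, 100]")
  id <- identities$percent_identity[match(calls$element_id,
                                          identities$element_id)]
  if (anyNA(id))
    stop("missing LTR identity for element(s): ",
         paste(calls$element_id[is.na(id)], collapse = ", "))
  k <- findInterval(id, bins, rightmost.closed = TRUE)
  out <- list()
  for (b in seq_len(length(bins) - 1L)) {
    sub <- calls[k == b, , drop = FALSE]
    tab <- tabulateVariants(sub)
    if (nrow(tab) == 0L) {
      tab <- data.frame(family = NA_character_, primer = NA_character_,
                        pbs_gapped = NA_character_,
                        ref_gapped = NA_character_, count = 0L,
                        edit_distance = NA_integer_, label = ".",
                        stringsAsFactors = FALSE)
    }
    tab$bin <- sprintf("[%g,%g%s", bins[b], bins[b + 1L],
                       if (b == length(bins) - 1L) "]" else ")")
    tab$bin_lo <- bins[b]; tab$bin_hi <- bins[b + 1L]
    tab$n_elements <- sum(k == b)
    out[[b]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
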