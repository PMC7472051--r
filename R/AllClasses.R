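#' FamilyConfig: repeat-name sets and primer candidates for one ERV family
#'
#' Maps RepeatMasker repeat names to their role within one ERV family
#' (internal vs LTR) and lists the candidate primer tRNAs for that
#' family, in priority order (the first name wins deterministic ties in
#' primer assignment). Aliases of the same repeat (e.g. a library alias
#' of an internal sequence) are handled by listing both names.
#'
#' @slot familyName single family identifier.
#' @slot internalNames repeat names annotated as internal sequence.
#' @slot ltrNames repeat names annotated as LTRs.
#' @slot primerCandidates candidate primer tRNA names (priority order).
#'
#' @export
setClass("FamilyConfig",
  representation(
    familyName = "character",
    internalNames = "character",
    ltrNames = "character",
    primerCandidates = "character"
  )
)

setValidity("FamilyConfig", function(object) {
  msg <- character(0)
  if (length(object@familyName) != 1L || !nzchar(object@familyName))
    msg <- c(msg, "familyName must be a single non-empty string")
  if (length(intersect(object@internalNames, object@ltrNames)) > 0L)
    msg <- c(msg, "internalNames and ltrNames must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a FamilyConfig
#'
#' @param familyName family identifier (e.g. `"ETnIIbeta3"`).
#' @param internalNames character vector of internal repeat names.
#' @param ltrNames character vector of LTR repeat names.
#' @param primerCandidates candidate primer tRNA names, priority order.
#' @return A [FamilyConfig-class] object.
#' @examples
#' familyConfig("ETnIIbeta3", c("MMETN", "MMETn-int"), "ERVB7_1-LTR_MM",
#'              c("Lys3-UUU", "Lys1/2-CUU"))
#' @export
familyConfig <- function(familyName, internalNames, ltrNames,
                         primerCandidates = character(0)) {
  new("FamilyConfig",
      familyName = as.character(familyName),
      internalNames = as.character(internalNames),
      ltrNames = as.character(ltrNames),
      primerCandidates = as.character(primerCandidates))
}

#' @describeIn familyConfig family name accessor
#' @param x a `FamilyConfig`.
#' @export
familyName <- function(x) x@familyName

#' @describeIn familyConfig internal repeat names accessor
#' @export
internalNames <- function(x) x@internalNames

#' @describeIn familyConfig LTR repeat names accessor
#' @export
ltrNames <- function(x) x@ltrNames

#' @describeIn familyConfig primer candidate accessor
#' @export
primerCandidates <- function(x) x@primerCandidates

setMethod("show", "FamilyConfig", function(object) {
  cat("FamilyConfig:", object@familyName, "\n")
  cat("  internal:", paste(object@internalNames, collapse = ", "), "\n")
  cat("  LTR:     ", paste(object@ltrNames, collapse = ", "), "\n")
  cat("  primers: ", paste(object@primerCandidates, collapse = ", "), "\n")
})

#' ElementSet: reconstructed full-length LTR-internal-LTR elements
#'
#' Holds the elements called from merged repeat fragments: their genomic
#' span (a [GenomicRanges::GRanges] with `element_id` and `family`
#' metadata columns), their oriented sequence (reverse-complemented for
#' minus-strand elements, so position 1 is the 5' end of the element
#' transcript), and element-local sub-spans for the left (5') LTR, the
#' right (3') LTR and the internal fragments between them. "Left" and
#' "right" are in element orientation, not genome orientation.
#'
#' @slot granges genomic spans, one per element.
#' @slot seqs oriented element sequences, named by element id.
#' @slot leftLTR element-local [IRanges::IRanges] of the 5' LTR.
#' @slot rightLTR element-local IRanges of the 3' LTR.
#' @slot internal element-local IRangesList of internal fragments.
#'
#' @export
setClass("ElementSet",
  representation(
    granges = "GRanges",
    seqs = "DNAStringSet",
    leftLTR = "IRanges",
    rightLTR = "IRanges",
    internal = "CompressedIRangesList"
  )
)

setValidity("ElementSet", function(object) {
  n <- length(object@granges)
  msg <- character(0)
  ids <- object@granges$element_id
  if (is.null(ids) || is.null(object@granges$family))
    return("granges must carry element_id and family metadata columns")
  if (anyDuplicated(ids))
    msg <- c(msg, "element ids must be unique")
  for (sl in c("seqs", "leftLTR", "rightLTR", "internal"))
    if (length(slot(object, sl)) != n)
      msg <- c(msg, sprintf("slot '%s' length differs from granges", sl))
  if (n > 0 && length(object@seqs) == n) {
    if (!identical(names(object@seqs), as.character(ids)))
      msg <- c(msg, "seqs must be named by element_id, in order")
    if (any(GenomicRanges::width(object@granges) !=
            Biostrings::width(object@seqs)))
      msg <- c(msg, "sequence widths must equal genomic span widths")
    if (length(object@leftLTR) == n && length(object@rightLTR) == n &&
        any(IRanges::end(object@leftLTR) > IRanges::start(object@rightLTR)))
      msg <- c(msg, "left LTR must precede right LTR in element orientation")
  }
  if (length(msg)) msg else TRUE
})

setMethod("length", "ElementSet", function(x) length(x@granges))

setMethod("names", "ElementSet", function(x) as.character(x@granges$element_id))

setMethod("show", "ElementSet", function(object) {
  cat("ElementSet with", length(object), "full-length elements\n")
  fams <- table(object@granges$family)
  for (f in names(fams)) cat("  ", f, ": ", fams[[f]], "\n", sep = "")
  if (length(object) > 0) {
    cat("First ids:", paste(head(names(object), 3), collapse = ", "), "\n")
  }
})

setMethod("[", "ElementSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x))
  new("ElementSet",
      granges = x@granges[i],
      seqs = x@seqs[i],
      leftLTR = x@leftLTR[i],
      rightLTR = x@rightLTR[i],
      internal = x@internal[i])
})

#' Accessors for ElementSet
#'
#' @param x an [ElementSet-class].
#' @return `elementIds` a character vector; `elementRanges` the genomic
#'   GRanges; `elementSeqs` the oriented DNAStringSet; `leftLTR`,
#'   `rightLTR` element-local IRanges; `internalRegions` an IRangesList.
#' @name ElementSet-accessors
NULL

#' @rdname ElementSet-accessors
#' @export
elementIds <- function(x) names(x)

#' @rdname ElementSet-accessors
#' @export
elementRanges <- function(x) x@granges

#' @rdname ElementSet-accessors
#' @export
elementSeqs <- function(x) x@seqs

#' @rdname ElementSet-accessors
#' @export
leftLTR <- function(x) x@leftLTR

#' @rdname ElementSet-accessors
#' @export
rightLTR <- function(x) x@rightLTR

#' @rdname ElementSet-accessors
#' @export
internalRegions <- function(x) x@internal

#' Extract the 5'-UTR scan window of each element
#'
#' Returns, per element, up to `windowLen` nucleotides immediately
#' downstream of the 5' LTR end in element orientation. This window
#' contains the 2-4 nt spacer and the 18-nt PBS, and is what the PBS
#' locator and tRF scanners operate on. Elements shorter than
#' LTR + window yield a truncated window with a warning.
#'
#' @param x an [ElementSet-class].
#' @param windowLen window length in nt (default 40).
#' @return A named `DNAStringSet`, one window per element.
#' @export
utrWindows <- function(x, windowLen = 40L) {
  stopifnot(is(x, "ElementSet"), windowLen >= 18)
  starts <- IRanges::end(x@leftLTR) + 1L
  avail <- Biostrings::width(x@seqs) - starts + 1L
  w <- pmin(as.integer(windowLen), avail)
  if (any(w < windowLen))
    warning(sum(w < windowLen), " element(s) have a truncated 5'-UTR window")
  if (any(w < 1))
    stop("element(s) with no sequence downstream of the 5' LTR: ",
         paste(names(x)[w < 1], collapse = ", "))
  res <- Biostrings::subseq(x@seqs, start = starts, width = w)
  names(res) <- names(x)
  res
}
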