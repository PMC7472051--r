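#' Read RepeatMasker .out annotations
#'
#' Parses the standard RepeatMasker `.out` layout: three header lines
#' followed by whitespace-delimited records with 1-based inclusive
#' coordinates and strand given as `+` or `C` (complement). Coordinates
#' are stored in the returned [GenomicRanges::GRanges] (1-based
#' inclusive, the Bioconductor convention); `C` becomes `-`. Records are
#' kept in file order.
#'
#' @param path path to a `.out` file.
#' @return A `GRanges` with metadata columns `repeat_name`, `role`
#'   (initially `"other"`, see [assignRoles()]) and `family` (`NA`).
#' @export
readRepeatMaskerOut <- function(path) {
  lines <- readLines(path)
  if (length(lines) <= 3L) return(emptyRepeatGRanges())
  body <- lines[-(1:3)]
  body_idx <- which(nzchar(trimws(body)))
  if (length(body_idx) == 0L) return(emptyRepeatGRanges())
  recs <- strsplit(trimws(body[body_idx]), "[[:space:]]+")
  chrom <- character(length(recs)); beg <- integer(length(recs))
  end <- integer(length(recs)); strand <- character(length(recs))
  rname <- character(length(recs))
  for (k in seq_along(recs)) {
    f <- recs[[k]]
    line_no <- 3L + body_idx[k]
    if (length(f) < 10L)
      stop("malformed RepeatMasker record at line ", line_no,
           ": expected >= 10 fields, got ", length(f))
    b <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
    if (is.na(b) || is.na(e) || b < 1L || e < b)
      stop("malformed RepeatMasker record at line ", line_no,
           ": bad coordinates '", f[6], "', '", f[7], "'")
    if (!f[9] %in% c("+", "C"))
      stop("malformed RepeatMasker record at line ", line_no,
           ": strand must be '+' or 'C', got '", f[9], "'")
    chrom[k] <- f[5]; beg[k] <- b; end[k] <- e
    strand[k] <- if (f[9] == "C") "-" else "+"
    rname[k] <- f[10]
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(beg, end), strand = strand,
                         repeat_name = rname, role = "other",
                         family = NA_character_)
}

emptyRepeatGRanges <- function() {
  GenomicRanges::GRanges(character(0), IRanges::IRanges(),
                         repeat_name = character(0), role = character(0),
                         family = character(0))
}

#' Read / write BED6 repeat annotations
#'
#' BED uses 0-based half-open coordinates; the conversion to the
#' in-memory 1-based GRanges representation happens here and only here.
#' The BED name column becomes `repeat_name`; the score column is
#' ignored on input and written as 0.
#'
#' @param path file path.
#' @return `readBed`: a `GRanges` with `repeat_name`, `role`, `family`
#'   metadata columns.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(emptyRepeatGRanges())
  recs <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(recs)
  if (any(nf < 6L))
    stop("BED line ", which(nf < 6L)[1],
         " has fewer than 6 columns (BED6 required)")
  m <- do.call(rbind, lapply(recs, `[`, 1:6))
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  if (any(is.na(start0)) || any(is.na(end0)) || any(start0 < 0) ||
      any(end0 <= start0))
    stop("BED line ", which(is.na(start0) | is.na(end0) | start0 < 0 |
                            end0 <= start0)[1], " has invalid coordinates")
  if (!all(m[, 6] %in% c("+", "-")))
    stop("BED strand column must be '+' or '-'")
  GenomicRanges::GRanges(m[, 1], IRanges::IRanges(start0 + 1L, end0),
                         strand = m[, 6], repeat_name = m[, 4],
                         role = "other", family = NA_character_)
}

#' @rdname readBed
#' @param gr a `GRanges`; the written name column is `repeat_name` if
#'   present, else `element_id`, else `"."`.
#' @export
writeBed <- function(gr, path) {
  nm <- gr$repeat_name
  if (is.null(nm)) nm <- gr$element_id
  if (is.null(nm)) nm <- rep(".", length(gr))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm, score = 0L,
    strand = as.character(GenomicRanges::strand(gr)))
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. Input sequences are uppercased and
#' must use the alphabet A/C/G/T/N after uppercasing; duplicate record
#' names are an error. Reading back a written file recovers the same
#' name -> sequence mapping regardless of line wrapping.
#'
#' @param path file path.
#' @return `readFasta`: a named `DNAStringSet`.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence name(s) in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  chr <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad))
    stop("sequence(s) with letters outside A/C/G/T/N: ",
         paste(names(x)[bad], collapse = ", "))
  setNames(Biostrings::DNAStringSet(chr), names(x))
}

#' @rdname readFasta
#' @param seqs a named `DNAStringSet` or named character vector.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read / write tab-separated tables with a header line
#'
#' @param path file path.
#' @param df a data.frame.
#' @return `readTsv`: a data.frame.
#' @export
readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "")
}

#' @rdname readTsv
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' @param path file path.
#' @param tree an [ape::phylo] tree.
#' @return `readNewick`: a `phylo` object.
#' @export
readNewick <- function(path) ape::read.tree(path)

#' @rdname readNewick
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write a family configuration file
#'
#' The family configuration is a plain-text key-value format, one block
#' per family:
#' ```
#' [ETnIIbeta3]
#' internal = MMETN, MMETn-int
#' ltr = ERVB7_1-LTR_MM
#' primers = Lys3-UUU, Lys1/2-CUU
#' ```
#' Repeat-name aliases are data: list both names under `internal` (or
#' `ltr`).
#'
#' @param path file path.
#' @return `readFamilyConfig`: a named list of [FamilyConfig-class].
#' @export
readFamilyConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur <- NULL
  flush <- function(cur, out) {
    if (is.null(cur)) return(out)
    fc <- familyConfig(cur$name, cur$internal %||% character(0),
                       cur$ltr %||% character(0),
                       cur$primers %||% character(0))
    out[[cur$name]] <- fc
    out
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      out <- flush(cur, out)
      cur <- list(name = sub("^\\[(.+)\\]$", "\\1", ln))
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) stop("family config entry before any [family] header")
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(strsplit(sub("^[^=]*=", "", ln), ",")[[1]])
      val <- val[nzchar(val)]
      if (!key %in% c("internal", "ltr", "primers"))
        stop("unknown family config key '", key, "'")
      cur[[key]] <- val
    } else {
      stop("unparseable family config line: '", ln, "'")
    }
  }
  flush(cur, out)
}

#' @rdname readFamilyConfig
#' @param cfgs a named list of `FamilyConfig`.
#' @export
writeFamilyConfig <- function(cfgs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fc in cfgs) {
    writeLines(sprintf("[%s]", familyName(fc)), con)
    writeLines(sprintf("internal = %s",
                       paste(internalNames(fc), collapse = ", ")), con)
    writeLines(sprintf("ltr = %s", paste(ltrNames(fc), collapse = ", ")), con)
    writeLines(sprintf("primers = %s",
                       paste(primerCandidates(fc), collapse = ", ")), con)
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign LTR/internal roles and family labels to repeat features
#'
#' Roles are derived by exact string match of `repeat_name` against the
#' family configuration; names absent from every family keep
#' `role = "other"` and `family = NA`.
#'
#' @param gr a `GRanges` from [readBed()] or [readRepeatMaskerOut()].
#' @param cfgs a named list of [FamilyConfig-class].
#' @return The same `GRanges` with `role` and `family` filled in.
#' @export
assignRoles <- function(gr, cfgs) {
  role <- rep("other", length(gr))
  fam <- rep(NA_character_, length(gr))
  for (fc in cfgs) {
    i <- gr$repeat_name %in% internalNames(fc)
    l <- gr$repeat_name %in% ltrNames(fc)
    role[i] <- "internal"; role[l] <- "LTR"
    fam[i | l] <- familyName(fc)
  }
  gr$role <- role
  gr$family <- fam
  gr
}
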