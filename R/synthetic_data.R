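#' Configure a synthetic ERV genome simulation
#'
#' Builds the configuration for [simulateERVGenome()]: a genome of
#' random background sequence with planted LTR-spacer-PBS-internal-LTR
#' elements whose PBS variants, primer usage (including a switch
#' fraction to an alternate primer), LTR divergence, annotation
#' fragmentation, strand mixture and decoy fragments are all known
#' ground truth. Variant and switch fractions are allocated exactly
#' (largest-remainder rounding), so planted counts are deterministic
#' given the configuration.
#'
#' Each entry of `families` is a list with fields:
#' \describe{
#'   \item{name}{family name.}
#'   \item{nElements}{planted full-length elements.}
#'   \item{primer}{primer tRNA name.}
#'   \item{altPrimer, switchFraction}{optional alternate primer and the
#'     exact fraction of elements carrying its perfect PBS (primer
#'     switching).}
#'   \item{variants}{list of `list(name, edits, freq)`; `edits` is a
#'     data.frame with columns `op` (`sub`/`ins`/`del`), `pos` (1..18)
#'     and `base`, applied to the family's perfect PBS; `NULL` edits
#'     mean the perfect PBS. Frequencies must sum to 1. Indel edits
#'     must sit at interior positions 2..17 so planted variants stay
#'     unambiguous under fit alignment.}
#'   \item{ltrDivergence}{per-position mutation probability applied to
#'     the 3' LTR (default 0); may be overridden per variant via a
#'     `divergence` field.}
#' }
#'
#' @param seed RNG seed; all simulator randomness flows from it.
#' @param families list of family specs (see Details).
#' @param ltrLen,internalLen LTR and internal-core lengths in nt.
#' @param spacerRange inclusive range of the LTR-PBS spacer (default
#'   2-4 nt).
#' @param utrExtra random 5'-UTR filler nt between PBS and internal
#'   core (default 20).
#' @param interElementGap background nt between planted items
#'   (default 1000).
#' @param internalDivergence per-position mutation probability of each
#'   element's internal core relative to the family consensus
#'   (default 0.01), providing phylogenetic signal.
#' @param fragmentation list `(prob, gapRange)`: probability that an
#'   element's internal annotation is emitted as two features separated
#'   by an annotation gap drawn uniformly from `gapRange`; gaps above
#'   the merge limit make the element unrecoverable by design.
#' @param decoys list of counts: `solo_ltr`, `internal_only`,
#'   `short_fragment` (a 400-nt LTR piece).
#' @param minusStrandFraction exact fraction of elements planted on
#'   the minus strand.
#' @return A validated config list of class `erv_sim_config`.
#' @export
simulationConfig <- function(seed = 1L, families = list(),
                             ltrLen = 300L, internalLen = 1500L,
                             spacerRange = c(2L, 4L), utrExtra = 20L,
                             interElementGap = 1000L,
                             internalDivergence = 0.01,
                             fragmentation = list(prob = 0,
                                                  gapRange = c(100L, 400L)),
                             decoys = list(solo_ltr = 0L,
                                           internal_only = 0L,
                                           short_fragment = 0L),
                             minusStrandFraction = 0) {
  stopifnot(ltrLen > 0, internalLen > 0, utrExtra >= 0,
            interElementGap > 0, length(families) >= 0)
  for (f in families) {
    stopifnot(!is.null(f$name), !is.null(f$nElements), !is.null(f$primer))
    vs <- f$variants %||% list(list(name = "perfect", edits = NULL, freq = 1))
    fr <- vapply(vs, function(v) v$freq, 0)
    if (abs(sum(fr) - 1) > 1e-9)
      stop("variant frequencies of family '", f$name,
           "' must sum to 1 (got ", sum(fr), ")")
    for (v in vs) {
      if (is.null(v$edits)) next
      stopifnot(all(v$edits$op %in% c("sub", "ins", "del")),
                all(v$edits$pos >= 1L), all(v$edits$pos <= 18L))
      ind <- v$edits$op %in% c("ins", "del")
      if (any(v$edits$pos[ind] < 2L | v$edits$pos[ind] > 17L))
        stop("indel edits must sit at interior PBS positions 2..17 ",
             "(variant '", v$name, "' of family '", f$name, "')")
    }
    sw <- f$switchFraction %||% 0
    if (sw > 0 && is.null(f$altPrimer))
      stop("family '", f$name, "' has a switch fraction but no altPrimer")
  }
  structure(list(seed = as.integer(seed), families = families,
                 ltrLen = as.integer(ltrLen),
                 internalLen = as.integer(internalLen),
                 spacerRange = as.integer(spacerRange),
                 utrExtra = as.integer(utrExtra),
                 interElementGap = as.integer(interElementGap),
                 internalDivergence = internalDivergence,
                 fragmentation = fragmentation, decoys = decoys,
                 minusStrandFraction = minusStrandFraction),
            class = "erv_sim_config")
}

# exact multinomial allocation by largest remainder, ties by index
largestRemainder <- function(n, freqs) {
  raw <- n * freqs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(-(raw - base), seq_along(freqs))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample one integer from [lo, hi], safe for degenerate ranges
sampleRange <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(sample(seq.int(lo, hi), 1L))
}

mutateSeq <- function(seq, prob) {
  if (prob <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < prob)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

applyVariantEdits <- function(perfect, edits) {
  if (is.null(edits) || nrow(edits) == 0L) return(perfect)
  chars <- strsplit(perfect, "", fixed = TRUE)[[1]]
  out <- as.list(chars)
  for (k in seq_len(nrow(edits))) {
    p <- edits$pos[k]
    switch(edits$op[k],
      sub = { out[[p]] <- edits$base[k] },
      del = { out[[p]] <- character(0) },
      ins = { out[[p]] <- c(out[[p]], edits$base[k]) })
  }
  paste(unlist(out), collapse = "")
}

#' Simulate a genome with planted ERV elements and known truth
#'
#' Generates (i) a genome FASTA with one chromosome per family plus a
#' decoy chromosome, (ii) BED6 annotations emulating fragmented
#' RepeatMasker output, (iii) a primer tRNA FASTA (random CCA-tailed
#' 25-mers; real tRNA libraries can be supplied for real runs), (iv) a
#' per-element truth table, and (v) the matching family configuration.
#' Identical seeds give byte-identical outputs. The generator
#' guarantees that no planted PBS variant is at least as close to a
#' non-target primer's perfect PBS as to its own (assignment is
#' unambiguous by construction; violated draws are resampled).
#'
#' @param cfg a config from [simulationConfig()].
#' @param outDir if non-`NULL`, writes `genome.fa`, `annotations.bed`,
#'   `trnas.fa`, `truth.tsv` and `families.cfg` there.
#' @return A list with `genome` (`DNAStringSet`), `annotations`
#'   (`GRanges`), `trnas` (`DNAStringSet`), `truth` (data.frame) and
#'   `familyConfigs` (named list of [FamilyConfig-class]).
#' @export
simulateERVGenome <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "erv_sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(cfg$seed)

  primer_names <- unique(unlist(lapply(cfg$families, function(f)
    c(f$primer, f$altPrimer))))
  # random CCA-tailed tRNA 3'-ends; resample until every planted
  # variant is strictly closer to its own primer than to any other
  trnas <- NULL
  for (attempt in seq_len(100L)) {
    cand <- setNames(vapply(primer_names, function(p)
      paste0(randomDNA(22L), "CCA"), ""), primer_names)
    if (plantedUnambiguous(cfg, cand)) { trnas <- cand; break }
  }
  if (is.null(trnas))
    stop("could not draw primer tRNAs with unambiguous planted variants")
  pbs_of <- perfectPBS(Biostrings::DNAStringSet(trnas))

  chroms <- list(); ann <- list(); truth <- list(); fam_cfgs <- list()
  chrom_i <- 0L
  for (f in cfg$families) {
    chrom_i <- chrom_i + 1L
    chrom <- sprintf("chr%d", chrom_i)
    fam <- f$name
    int_name <- paste0(fam, "-int"); ltr_name <- paste0(fam, "-LTR")
    fam_cfgs[[fam]] <- familyConfig(fam, int_name, ltr_name,
                                    c(f$primer, f$altPrimer))
    ltr_cons <- randomDNA(cfg$ltrLen)
    int_cons <- randomDNA(cfg$internalLen)
    n <- f$nElements
    vs <- f$variants %||% list(list(name = "perfect", edits = NULL, freq = 1))
    sw <- f$switchFraction %||% 0
    n_switch <- largestRemainder(n, c(sw, 1 - sw))[1]
    n_var <- largestRemainder(n - n_switch,
                              vapply(vs, function(v) v$freq, 0))
    assign_var <- c(rep(0L, n_switch),
                    rep(seq_along(vs), n_var)) # 0 = switched
    assign_var <- sample(assign_var, n)
    n_minus <- largestRemainder(n, c(cfg$minusStrandFraction,
                                     1 - cfg$minusStrandFraction))[1]
    minus <- sample(c(rep(TRUE, n_minus), rep(FALSE, n - n_minus)), n)
    seq_parts <- character(0); pos <- 0L
    for (k in seq_len(n)) {
      vi <- assign_var[k]
      if (vi == 0L) {
        primer <- f$altPrimer; vname <- "switch"
        pbs <- pbs_of[[f$altPrimer]]
      } else {
        primer <- f$primer; vname <- vs[[vi]]$name
        pbs <- applyVariantEdits(pbs_of[[f$primer]], vs[[vi]]$edits)
      }
      div <- if (vi > 0L && !is.null(vs[[vi]]$divergence))
        vs[[vi]]$divergence else (f$ltrDivergence %||% 0)
      spacer_n <- sampleRange(cfg$spacerRange[1], cfg$spacerRange[2])
      left <- ltr_cons
      right <- mutateSeq(ltr_cons, div)
      core <- mutateSeq(int_cons, cfg$internalDivergence)
      # the 4 nt downstream of the PBS pair tRNA positions 19-22 (the
      # retroviral initiation complex pairs the first 22 tRNA nt), so a
      # 22-nt tRF3b finds its full site on an unmutated element
      tseq <- as.character(trnas[[primer]])
      ext4 <- substr(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(tseq, nchar(tseq) - 21L,
                                     nchar(tseq))))), 19L, 22L)
      el <- paste0(left, randomDNA(spacer_n), pbs, ext4,
                   randomDNA(cfg$utrExtra), core, right)
      L <- nchar(el)
      gstart <- pos + cfg$interElementGap + 1L
      seq_parts <- c(seq_parts, randomDNA(cfg$interElementGap),
                     if (minus[k]) as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(el))) else el)
      # local annotation spans (element orientation, 1-based)
      ltrA <- c(1L, cfg$ltrLen)
      intA <- c(cfg$ltrLen + 1L, L - cfg$ltrLen)
      ltrB <- c(L - cfg$ltrLen + 1L, L)
      frag_gap <- 0L
      feats <- list(list(ltr_name, ltrA, "LTR"))
      frag <- stats::runif(1) < (cfg$fragmentation$prob %||% 0)
      if (frag) {
        g <- sampleRange(cfg$fragmentation$gapRange[1],
                         cfg$fragmentation$gapRange[2])
        wid <- intA[2] - intA[1] + 1L
        if (g + 2L < wid) {
          mid <- intA[1] + (wid - g) %/% 2L
          feats <- c(feats, list(list(int_name, c(intA[1], mid), "internal"),
                                 list(int_name, c(mid + g + 1L, intA[2]),
                                      "internal")))
          frag_gap <- g
        } else {
          feats <- c(feats, list(list(int_name, intA, "internal")))
        }
      } else {
        feats <- c(feats, list(list(int_name, intA, "internal")))
      }
      feats <- c(feats, list(list(ltr_name, ltrB, "LTR")))
      strand <- if (minus[k]) "-" else "+"
      for (ft in feats) {
        loc <- ft[[2]]
        gcoord <- if (minus[k]) c(gstart + L - loc[2], gstart + L - loc[1])
                  else c(gstart + loc[1] - 1L, gstart + loc[2] - 1L)
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = chrom, start = gcoord[1], end = gcoord[2],
          name = ft[[1]], strand = strand, stringsAsFactors = FALSE)
      }
      # a >merge-limit annotation gap leaves two clusters, each missing
      # a flanking LTR -> the element cannot survive assembly
      survives <- frag_gap <= 500L
      truth[[length(truth) + 1L]] <- data.frame(
        type = "element", family = fam, chrom = chrom,
        start = gstart, end = gstart + L - 1L, strand = strand,
        primer = primer, variant = vname, pbs_seq = pbs,
        spacer = spacer_n, divergence = div, frag_gap = frag_gap,
        expected_survival = survives, stringsAsFactors = FALSE)
      pos <- pos + cfg$interElementGap + L
    }
    chroms[[chrom]] <- paste0(paste(seq_parts, collapse = ""),
                              randomDNA(cfg$interElementGap))
  }

  # decoys on their own chromosome, attributed to the first family
  dk <- cfg$decoys
  n_decoy <- (dk$solo_ltr %||% 0L) + (dk$internal_only %||% 0L) +
    (dk$short_fragment %||% 0L)
  if (n_decoy > 0L && length(cfg$families) > 0L) {
    chrom_i <- chrom_i + 1L
    chrom <- sprintf("chr%d", chrom_i)
    f <- cfg$families[[1]]
    fam <- f$name
    int_name <- paste0(fam, "-int"); ltr_name <- paste0(fam, "-LTR")
    seq_parts <- character(0); pos <- 0L
    kinds <- c(rep("solo_ltr", dk$solo_ltr %||% 0L),
               rep("internal_only", dk$internal_only %||% 0L),
               rep("short_fragment", dk$short_fragment %||% 0L))
    for (kind in kinds) {
      piece <- switch(kind,
        solo_ltr = randomDNA(cfg$ltrLen),
        internal_only = randomDNA(cfg$internalLen),
        short_fragment = randomDNA(400L))
      nmrole <- switch(kind,
        solo_ltr = c(ltr_name, "LTR"),
        internal_only = c(int_name, "internal"),
        short_fragment = c(ltr_name, "LTR"))
      gstart <- pos + cfg$interElementGap + 1L
      seq_parts <- c(seq_parts, randomDNA(cfg$interElementGap), piece)
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = chrom, start = gstart, end = gstart + nchar(piece) - 1L,
        name = nmrole[1], strand = "+", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        type = kind, family = fam, chrom = chrom,
        start = gstart, end = gstart + nchar(piece) - 1L, strand = "+",
        primer = NA_character_, variant = NA_character_,
        pbs_seq = NA_character_, spacer = NA_integer_,
        divergence = NA_real_, frag_gap = 0L,
        expected_survival = FALSE, stringsAsFactors = FALSE)
      pos <- pos + cfg$interElementGap + nchar(piece)
    }
    chroms[[chrom]] <- paste0(paste(seq_parts, collapse = ""),
                              randomDNA(cfg$interElementGap))
  }

  genome <- Biostrings::DNAStringSet(unlist(chroms))
  truth_df <- do.call(rbind, truth)
  ann_df <- do.call(rbind, ann)
  ann_df <- ann_df[order(ann_df$chrom, ann_df$start, ann_df$end), ,
                   drop = FALSE]
  annotations <- GenomicRanges::GRanges(
    ann_df$chrom, IRanges::IRanges(ann_df$start, ann_df$end),
    strand = ann_df$strand, repeat_name = ann_df$name,
    role = "other", family = NA_character_)
  annotations <- assignRoles(annotations, fam_cfgs)
  trna_set <- Biostrings::DNAStringSet(trnas)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFasta(genome, file.path(outDir, "genome.fa"))
    writeBed(annotations, file.path(outDir, "annotations.bed"))
    writeFasta(trna_set, file.path(outDir, "trnas.fa"))
    writeTsv(truth_df, file.path(outDir, "truth.tsv"))
    writeFamilyConfig(fam_cfgs, file.path(outDir, "families.cfg"))
  }
  list(genome = genome, annotations = annotations, trnas = trna_set,
       truth = truth_df, familyConfigs = fam_cfgs)
}

# check the generator invariant: every planted variant is strictly
# closer (unit-cost edit distance) to its target primer's perfect PBS
# than to any other primer's
plantedUnambiguous <- function(cfg, trnas) {
  pbs <- perfectPBS(Biostrings::DNAStringSet(trnas))
  for (f in cfg$families) {
    prims <- c(f$primer, f$altPrimer)
    vs <- f$variants %||% list(list(name = "perfect", edits = NULL, freq = 1))
    planted <- c(
      lapply(vs, function(v)
        list(seq = applyVariantEdits(pbs[[f$primer]], v$edits),
             target = f$primer,
             n_edits = if (is.null(v$edits)) 0L else nrow(v$edits))),
      if (!is.null(f$altPrimer))
        list(list(seq = pbs[[f$altPrimer]], target = f$altPrimer,
                  n_edits = 0L)))
    # planted variants must be pairwise distinct sequences (an edit
    # that recreates the perfect base would silently merge variants)
    if (anyDuplicated(vapply(planted, function(pl) pl$seq, "")))
      return(FALSE)
    for (pl in planted) {
      d_target <- globalAlign(pl$seq, pbs[[pl$target]])$cost
      # a planted edit that recreates the reference base would make the
      # variant sit closer to the target than specified
      if (d_target != pl$n_edits) return(FALSE)
      for (other in setdiff(names(pbs), pl$target))
        if (globalAlign(pl$seq, pbs[[other]])$cost <= d_target)
          return(FALSE)
    }
  }
  TRUE
}

#' Compare pipeline output against the planted truth
#'
#' @param elements the assembled [ElementSet-class] (all families).
#' @param calls PBS calls from [locatePBS()] for those elements.
#' @param truth the truth table from [simulateERVGenome()].
#' @return A list: `recall` and `precision` of element recovery at
#'   exact planted coordinates, `primer_accuracy` and
#'   `pbs_seq_accuracy` over recovered elements, `variant_count_error`
#'   (sum of absolute per-variant count differences), and
#'   `n_expected`, `n_recovered`.
#' @export
evaluateRecovery <- function(elements, calls, truth) {
  te <- truth[truth$type == "element", , drop = FALSE]
  expected <- te[te$expected_survival, , drop = FALSE]
  tkey <- sprintf("%s:%d-%d:%s", expected$chrom, expected$start,
                  expected$end, expected$strand)
  gr <- elementRanges(elements)
  ekey <- sprintf("%s:%d-%d:%s", as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr), GenomicRanges::end(gr),
                  as.character(GenomicRanges::strand(gr)))
  hit <- tkey %in% ekey
  recall <- if (nrow(expected)) mean(hit) else NA_real_
  precision <- if (length(ekey)) mean(ekey %in% tkey) else NA_real_
  m <- match(ekey, tkey)
  rec_truth <- expected[m[!is.na(m)], , drop = FALSE]
  rec_ids <- names(elements)[!is.na(m)]
  cc <- calls[match(rec_ids, calls$element_id), , drop = FALSE]
  obs_seq <- gsub("-", "", cc$pbs_gapped, fixed = TRUE)
  primer_acc <- if (nrow(cc)) mean(cc$primer_assigned == rec_truth$primer)
                else NA_real_
  seq_acc <- if (nrow(cc)) mean(obs_seq == rec_truth$pbs_seq) else NA_real_
  tv <- table(paste(expected$family, expected$primer, expected$pbs_seq))
  ov <- table(paste(cc$family, cc$primer_assigned, obs_seq))
  keys <- union(names(tv), names(ov))
  vce <- sum(abs(ifelse(keys %in% names(tv), as.integer(tv[keys]), 0L) -
                 ifelse(keys %in% names(ov), as.integer(ov[keys]), 0L)))
  list(recall = recall, precision = precision,
       primer_accuracy = primer_acc, pbs_seq_accuracy = seq_acc,
       variant_count_error = vce,
       n_expected = nrow(expected), n_recovered = sum(!is.na(m)))
}
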