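#' Run the full PBS-variation pipeline
#'
#' Orchestrates assembly, PBS calling, variant tabulation, mutation
#' spectrum, tRF susceptibility, LTR-identity dating with age
#' stratification, and a bootstrapped NJ tree, per family. All outputs
#' are deterministic given `seed`; filter counts are logged via
#' `message()` and also returned, and always satisfy
#' input = kept + dropped at every stage.
#'
#' Per family, `outDir` receives `<family>.elements.bed`,
#' `<family>.elements.fa`, `<family>.calls.tsv`, `<family>.variants.tsv`
#' (the per-family variant table with P/C labels),
#' `<family>.susceptibility.tsv`, `<family>.identity.tsv`,
#' `<family>.age_strata.tsv`, `<family>.spectrum.tsv` and, for
#' families with at least 3 elements, `<family>.nwk` (bootstrapped NJ
#' tree of the PBS-anchored 5'-UTR windows, leaves labelled `|P`/`|C`).
#'
#' @param annotations repeat annotations: a `GRanges`, or a path to a
#'   BED6 or RepeatMasker `.out` file (`.out` detected by extension).
#' @param genome a named `DNAStringSet` or FASTA path.
#' @param trnas primer tRNA 3'-ends, named `DNAStringSet` or FASTA
#'   path.
#' @param familyConfigs named list of [FamilyConfig-class] or a config
#'   file path (see [readFamilyConfig()]).
#' @param outDir output directory (created if missing); `NULL` skips
#'   file output.
#' @param seed seed for the bootstrap (default 1).
#' @param maxGap,minLen assembly parameters (defaults 500/500).
#' @param windowLen,offsetRange,maxReportDistance PBS parameters.
#' @param trfLengths tRF lengths scored (default `c(18, 22)`).
#' @param bins LTR-identity bin edges for age stratification.
#' @param bootstrapReplicates NJ bootstrap replicates (default 100).
#' @param tolerantPositions optional PBS positions for
#'   [annotatePositions()].
#' @return Invisibly, a list per family with `elements`, `calls`,
#'   `variants`, `spectrum`, `susceptibility`, `identity`, `strata`,
#'   `tree`, `log`, plus `soloLtrs` and `log` at the top level.
#' @export
runAll <- function(annotations, genome, trnas, familyConfigs,
                   outDir = NULL, seed = 1L,
                   maxGap = 500L, minLen = 500L,
                   windowLen = 40L, offsetRange = c(0L, 10L),
                   maxReportDistance = 8L, trfLengths = c(18L, 22L),
                   bins = c(0, 90, 95, 100), bootstrapReplicates = 100L,
                   tolerantPositions = integer(0)) {
  if (is.character(genome)) genome <- readFasta(genome)
  if (is.character(trnas)) trnas <- readFasta(trnas)
  if (is.character(familyConfigs)) familyConfigs <-
    readFamilyConfig(familyConfigs)
  if (is.character(annotations)) {
    annotations <- if (grepl("\\.out$", annotations))
      readRepeatMaskerOut(annotations) else readBed(annotations)
  }
  annotations <- assignRoles(annotations, familyConfigs)
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  all_solo <- list()
  for (fc in familyConfigs) {
    fam <- familyName(fc)
    feats <- annotations[!is.na(annotations$family) &
                         annotations$family == fam]
    msg <- function(...) message("[", fam, "] ", ...)
    msg(length(feats), " annotated fragments")
    clusters <- mergeFragments(feats, maxGap = maxGap)
    msg(length(clusters), " merged clusters")
    solo <- soloLtrs(clusters)
    all_solo[[fam]] <- solo
    called <- callElements(clusters, genome, fam, minLen = minLen)
    el <- called$elements
    lg <- called$log
    msg(lg[["kept"]], " full-length elements (",
        lg[["dropped_short"]], " dropped short, ",
        lg[["dropped_missing_ltr"]], " missing flanking LTRs, ",
        length(solo), " solo-LTR fragments)")
    fam_res <- list(elements = el, log = lg)
    if (length(el) > 0) {
      prim <- primerCandidates(fc)
      prim <- prim[prim %in% names(trnas)]
      if (length(prim) == 0L)
        stop("pipeline stage pbs, family ", fam,
             ": no primer candidate found in the tRNA library")
      fam_trnas <- trnas[prim]
      calls <- locatePBS(el, fam_trnas, windowLen = windowLen,
                         offsetRange = offsetRange,
                         maxReportDistance = maxReportDistance)
      tabs <- list()
      for (p in unique(calls$primer_assigned[!calls$unassigned])) {
        tb <- tabulateVariants(calls, family = fam, primer = p,
                               perfect = perfectPBS(fam_trnas[[p]]))
        if (length(tolerantPositions))
          tb <- annotatePositions(tb, tolerantPositions)
        tabs[[p]] <- tb
      }
      variants <- if (length(tabs)) do.call(rbind, c(tabs,
                    make.row.names = FALSE)) else NULL
      spectrum <- mutationSpectrum(calls[!calls$unassigned, , drop = FALSE])
      susc <- scoreElementTRFs(el, fam_trnas, lengths = trfLengths,
                               windowLen = windowLen)
      ident <- ltrIdentity(el)
      strata <- stratifyByAge(calls, ident, bins = bins)
      tree <- NULL
      if (length(el) >= 3L) {
        wins <- utrWindows(el, windowLen)
        wchr <- as.character(wins)
        if (length(unique(nchar(wchr))) == 1L) {
          tree <- bootstrapTree(setNames(wchr, names(wins)),
                                replicates = bootstrapReplicates,
                                seed = seed)
        } else {
          msg("skipping tree: truncated 5'-UTR windows of unequal length")
        }
      }
      fam_res <- c(fam_res, list(calls = calls, variants = variants,
                                 spectrum = spectrum,
                                 susceptibility = susc,
                                 identity = ident, strata = strata,
                                 tree = tree))
      if (!is.null(outDir)) {
        pre <- file.path(outDir, fam)
        writeBed(elementRanges(el), paste0(pre, ".elements.bed"))
        writeFasta(elementSeqs(el), paste0(pre, ".elements.fa"))
        writeTsv(calls, paste0(pre, ".calls.tsv"))
        if (!is.null(variants))
          writeTsv(variants, paste0(pre, ".variants.tsv"))
        writeTsv(susc, paste0(pre, ".susceptibility.tsv"))
        writeTsv(ident, paste0(pre, ".identity.tsv"))
        writeTsv(strata, paste0(pre, ".age_strata.tsv"))
        writeTsv(spectrumToTable(spectrum), paste0(pre, ".spectrum.tsv"))
        if (!is.null(tree)) {
          labels <- variantLeafLabels(
            calls, if (is.null(variants)) tabulateVariants(calls)
                   else variants)
          writeAnnotatedNewick(tree, labels, paste0(pre, ".nwk"))
        }
      }
    }
    results[[fam]] <- fam_res
  }
  results$soloLtrs <- all_solo
  results$log <- do.call(rbind, lapply(
    names(results)[names(results) %in% names(familyConfigs)],
    function(f) data.frame(family = f, t(results[[f]]$log))))
  invisible(results)
}

spectrumToTable <- function(sp) {
  data.frame(
    metric = c(paste0("pos", 1:18), names(sp$classes12),
               "cpg_context", "editing_signature", "total_substitutions"),
    count = c(unname(sp$per_position), unname(sp$classes12),
              sp$cpg_context, sp$editing_signature,
              sp$total_substitutions),
    stringsAsFactors = FALSE)
}

#' Read a run configuration key-value file
#'
#' Simple `key = value` lines (one per line, `#` comments); list
#' values are comma-separated. Recognised keys: `annotations`,
#' `genome`, `trnas`, `family_config`, `out_dir`, `seed`, `max_gap`,
#' `min_len`, `window_len`, `offset_min`, `offset_max`,
#' `max_report_distance`, `trf_lengths`, `bins`,
#' `bootstrap_replicates`, `tolerant_positions`.
#'
#' @param path config file path.
#' @return A named list suitable for [do.call()] into [runAll()].
#' @export
readRunConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- setNames(as.list(vals), keys)
  for (f in c("annotations", "genome", "trnas", "family_config"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("run config file missing on disk: ", cfg[[f]])
  num <- function(x) if (is.null(x)) NULL else as.numeric(
    trimws(strsplit(x, ",")[[1]]))
  out <- list(annotations = cfg$annotations, genome = cfg$genome,
              trnas = cfg$trnas, familyConfigs = cfg$family_config,
              outDir = cfg$out_dir)
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$max_gap)) out$maxGap <- as.integer(cfg$max_gap)
  if (!is.null(cfg$min_len)) out$minLen <- as.integer(cfg$min_len)
  if (!is.null(cfg$window_len)) out$windowLen <- as.integer(cfg$window_len)
  if (!is.null(cfg$offset_min) || !is.null(cfg$offset_max))
    out$offsetRange <- c(as.integer(cfg$offset_min %||% 0),
                         as.integer(cfg$offset_max %||% 10))
  if (!is.null(cfg$max_report_distance))
    out$maxReportDistance <- as.integer(cfg$max_report_distance)
  if (!is.null(cfg$trf_lengths)) out$trfLengths <-
    as.integer(num(cfg$trf_lengths))
  if (!is.null(cfg$bins)) out$bins <- num(cfg$bins)
  if (!is.null(cfg$bootstrap_replicates))
    out$bootstrapReplicates <- as.integer(cfg$bootstrap_replicates)
  if (!is.null(cfg$tolerant_positions))
    out$tolerantPositions <- as.integer(num(cfg$tolerant_positions))
  out
}
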