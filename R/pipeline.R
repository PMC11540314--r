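## Config-driven end-to-end orchestration.
##
## One root seed flows to every stage through named substreams, so a
## rerun with the same config is reproducible stage by stage.  The
## demo pipeline simulates its own inputs; a phenotype CSV can be
## supplied instead of simulated traits.

#' Default pipeline configuration
#'
#' Scale parameters describe the default in-silico experiment: 5
#' chromosomes x 2 Mb, 343 F1 lines at 0.5x coverage with a 122-line
#' deep subset at 30x, per-parent heterozygous-site density 2e-4/bp,
#' 2.5 indels per line (66.5% deletions) of 250 kb - 1 Mb, and one
#' planted allelic + one planted dosage trait.  Analysis parameters
#' carry the method defaults: 50-SNP bins, depth >= 20 for phasing,
#' 90% link consistency, 0.75/1.25 dosage cutoffs, 1000 permutations,
#' alpha 0.05.
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    simulate = list(
      nChrom = 5L, chromLen = 2e6, hetDensity = 2e-4,
      nLines = 343L, deepLines = 122L,
      recombPerChrom = 1, indelRate = 2.5,
      indelSizeRange = c(250e3, 1e6), pDeletion = 0.665,
      parentDepthPd = 45, parentDepthPn = 65,
      deepDepth = 30, lowDepth = 0.5, errorRate = 0.005,
      covBinSize = 5e4, meanCov = 250,
      beta0 = 0, noiseSd = 1, nullTraits = character(0),
      qtls = data.frame(trait = c("trait_allelic", "trait_dosage"),
                        chrom = c("Chr02", "Chr04"),
                        start = c(4e5, 8e5), end = c(6e5, 1.2e6),
                        channel = c("Pd", "dosage"),
                        effect = c(0.8, 0.8),
                        stringsAsFactors = FALSE)),
    binSize = 50L, depthMin = 20, consistency = 0.9, minLines = 10L,
    minConcordance = 0.9, maxSwitches = 4L,
    lowCut = 0.75, highCut = 1.25, minRun = 2L,
    nPerm = 1000L, alpha = 0.05, minN = 20L, minMinor = 5L,
    channels = c("Pd", "Pn", "dosage"),
    phenoFile = NULL)
}

validateConfig <- function(config) {
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  stopifNot1(length(unknown) == 0, "unknown config key(s): %s",
             paste(unknown, collapse = ", "))
  if (!is.null(config$simulate)) {
    unknown <- setdiff(names(config$simulate), names(def$simulate))
    stopifNot1(length(unknown) == 0, "unknown simulate key(s): %s",
               paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(def, config)
  stopifNot1(cfg$binSize >= 1, "binSize must be >= 1")
  stopifNot1(cfg$nPerm >= 1, "nPerm must be >= 1")
  stopifNot1(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0,1)")
  stopifNot1(cfg$lowCut < cfg$highCut, "lowCut must be < highCut")
  stopifNot1(all(cfg$channels %in% c("Pd", "Pn", "dosage")),
             "channels must be among Pd, Pn, dosage")
  if (is.list(cfg$simulate$qtls) && !is.data.frame(cfg$simulate$qtls))
    cfg$simulate$qtls <- do.call(rbind, lapply(cfg$simulate$qtls,
                                               as.data.frame))
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Values in the file override [defaultConfig()]; unknown keys are
#' rejected before any computation.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readConfig <- function(path) {
  stopifNot1(file.exists(path), "config file not found: %s", path)
  validateConfig(yaml::read_yaml(path))
}

logMsg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[duoQTL] ", fmt), ...))
}

#' Run the full pipeline
#'
#' simulate -> select informative SNPs -> phase -> genotype -> line QC
#' -> dosage -> common markers -> single-channel scans -> combined scan
#' -> report.  Every stage draws its randomness from a named substream
#' of `config$seed`, logs its parameters and row counts, and (when
#' `outDir` is given) leaves its table on disk.
#'
#' @param config configuration list (see [defaultConfig()]) or a YAML
#'   path.
#' @param outDir optional output directory for the stage tables.
#' @param verbose emit progress messages (default TRUE).
#' @return list with the stage objects (`parents`, `pop`, `phased`,
#'   `binned`, `dosage`, `cm`, `pheno`, `scans`, `combined`), the
#'   combined QTL table `qtls`, and the summary `report`.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL,
                        verbose = TRUE) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- validateConfig(config)
  sim <- cfg$simulate
  seed <- cfg$seed

  logMsg(verbose, "simulate: %d chrom x %g bp, %d lines, seed %d",
         sim$nChrom, sim$chromLen, sim$nLines, seed)
  parents <- simulateParents(sim$nChrom, sim$chromLen, sim$hetDensity,
                             seed = stageSeed(seed, "simulate_parents"))
  pop <- simulateF1(parents, sim$nLines, sim$recombPerChrom, sim$indelRate,
                    sim$indelSizeRange, sim$pDeletion,
                    seed = stageSeed(seed, "simulate_f1"))
  deep <- head(pop@lines, sim$deepLines)

  pdCounts <- simulateParentCounts(parents, "Pd", sim$parentDepthPd,
                                   sim$errorRate,
                                   seed = stageSeed(seed, "parent_counts"))
  pnCounts <- simulateParentCounts(parents, "Pn", sim$parentDepthPn,
                                   sim$errorRate,
                                   seed = stageSeed(seed + 1L, "parent_counts"))
  pdGeno <- callParentGenotypes(pdCounts)
  pnGeno <- callParentGenotypes(pnCounts)
  info <- list(Pd = selectInformativeSnps(pdGeno, pnGeno, "Pd"),
               Pn = selectInformativeSnps(pdGeno, pnGeno, "Pn"))
  logMsg(verbose, "informative SNPs: Pd %d, Pn %d",
         nrow(info$Pd), nrow(info$Pn))

  deepCounts <- simulateAlleleCounts(parents, pop, deep, sim$deepDepth,
                                     sim$errorRate,
                                     seed = stageSeed(seed, "deep_counts"))
  lowCounts <- simulateAlleleCounts(parents, pop, pop@lines, sim$lowDepth,
                                    sim$errorRate,
                                    seed = stageSeed(seed, "low_counts"))

  phased <- list(); binned <- list(); refBinned <- list()
  for (pa in c("Pd", "Pn")) {
    mat <- inferInheritedAlleles(deepCounts, info[[pa]], cfg$depthMin)
    phased[[pa]] <- phaseHaplotypes(mat, info[[pa]], cfg$consistency,
                                    cfg$minLines)
    obs <- callSnpHaplotypes(lowCounts, phased[[pa]], info[[pa]])
    binned[[pa]] <- binGenotypes(obs, phased[[pa]], cfg$binSize,
                                 lines = pop@lines)
    refObs <- callSnpHaplotypes(deepCounts, phased[[pa]], info[[pa]])
    refBinned[[pa]] <- binGenotypes(refObs, phased[[pa]], cfg$binSize,
                                    lines = deep)
    logMsg(verbose, "%s: %d phased SNPs, %d markers", pa,
           nrow(phased[[pa]]@haplotypes), nrow(binned[[pa]]@markers))
  }

  depths <- lineDepths(lowCounts, nrow(parents@sites))
  qc <- qcSelectLines(binned$Pd, refBinned$Pd, depths,
                      cfg$minConcordance, cfg$maxSwitches)
  logMsg(verbose, "line QC: %d of %d lines retained (depth >= %.3f)",
         length(qc$selected), length(pop@lines), qc$threshold)

  covObj <- simulateBinCoverage(pop, sim$covBinSize, sim$meanCov,
                                seed = stageSeed(seed, "bin_coverage"))
  dosage <- callDosage(normalizeCoverage(covObj), covObj@bins,
                       cfg$lowCut, cfg$highCut, cfg$minRun)
  cm <- buildCommonMarkers(binned$Pd, binned$Pn, dosage,
                           lines = qc$selected)
  logMsg(verbose, "common markers: %d x %d lines", nrow(cm@markers),
         length(lineIds(cm)))

  pheno <- if (!is.null(cfg$phenoFile)) readPhenotypes(cfg$phenoFile) else
    simulatePhenotypes(pop, sim$qtls, sim$beta0, sim$noiseSd,
                       sim$nullTraits, seed = stageSeed(seed, "phenotypes"))
  traits <- setdiff(names(pheno), "line_id")

  scans <- list(); combined <- list(); k <- 0L
  for (tr in traits) {
    for (ch in cfg$channels) {
      k <- k + 1L
      scans[[paste(tr, ch, sep = ".")]] <-
        qtlScan(cm, pheno, tr, ch, cfg$nPerm,
                seed = stageSeed(seed + k, "perm"),
                minN = cfg$minN, minMinor = cfg$minMinor)
    }
    combined[[tr]] <- combinedScan(cm, pheno, tr, cfg$nPerm, cfg$alpha,
                                   cfg$minMinor,
                                   seed = stageSeed(seed + k, "pair_perm"))
  }
  qtls <- do.call(rbind, c(
    lapply(scans, function(s) s@qtls[, qtlResultCols[qtlResultCols %in%
                                                       names(s@qtls)]]),
    lapply(combined, function(s)
      s$qtls[, qtlResultCols[qtlResultCols %in% names(s$qtls)],
             drop = FALSE])))
  if (is.null(qtls)) qtls <- emptyQtlFrame()
  rownames(qtls) <- NULL
  logMsg(verbose, "QTLs called: %d", nrow(qtls))

  rep <- qtlReport(qtls, cm, pheno,
                   truth = if (is.null(cfg$phenoFile)) sim$qtls else NULL)

  out <- list(config = cfg, parents = parents, pop = pop, info = info,
              phased = phased, binned = binned, qc = qc, dosage = dosage,
              cm = cm, pheno = pheno, scans = scans, combined = combined,
              qtls = qtls, report = rep)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMarkerTable(binned$Pd, file.path(outDir, "pd_binned.tsv"), seed)
    writeMarkerTable(binned$Pn, file.path(outDir, "pn_binned.tsv"), seed)
    writeMarkerTable(dosage, file.path(outDir, "dosage.tsv"), seed)
    writeMarkerTable(cm, file.path(outDir, "common_markers.tsv"), seed)
    writePhenotypes(pheno, file.path(outDir, "phenotypes.csv"), seed)
    writeQtlResults(qtls, file.path(outDir, "qtl_results.tsv"), seed)
    write.table(rep$summary, file.path(outDir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Summarize QTL results per trait and channel/group
#'
#' Tabulates QTL counts, the mean and SD of the per-QTL variance
#' explained, and the joint variance explained by the peak markers of
#' all of a trait's QTLs within a channel.  When the planted truth is
#' supplied, interval-overlap recall (fraction of planted QTLs
#' overlapped by a called interval on the same chromosome) and
#' precision (fraction of called QTLs overlapping a planted one) are
#' added.
#'
#' @param qtls QTL result data.frame (single + combined rows).
#' @param cm the [CommonMarkers-class] table the scans used.
#' @param pheno phenotype data.frame.
#' @param truth optional planted-QTL data.frame (trait, chrom, start,
#'   end, channel, effect).
#' @return list with `summary` (data.frame) and, given truth,
#'   `recall` and `precision`.
#' @export
qtlReport <- function(qtls, cm, pheno, truth = NULL) {
  mk <- cm@markers
  lines <- lineIds(cm)
  combos <- unique(qtls[, c("trait", "channel_or_group")])
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    tr <- combos$trait[r]; ch <- combos$channel_or_group[r]
    q <- qtls[qtls$trait == tr & qtls$channel_or_group == ch, ]
    y <- pheno[[tr]][match(lines, pheno$line_id)]
    veAll <- if (ch %in% c("Pd", "Pn", "dosage")) {
      G <- encodeChannel(cm, ch)
      tryCatch(allQtlVariance(y, G, q$peak_marker), error = function(e) NA_real_)
    } else {
      st <- assignStates(cm)
      peaks <- unique(q$peak_marker)
      dat <- as.data.frame(lapply(peaks, function(p) st[p, ]),
                           col.names = paste0("m", seq_along(peaks)))
      cc <- complete.cases(dat) & !is.na(y)
      tryCatch(summary(lm(y[cc] ~ ., data = as.data.frame(
        lapply(dat[cc, , drop = FALSE], factor))))$adj.r.squared,
        error = function(e) NA_real_)
    }
    data.frame(trait = tr, channel_or_group = ch, n_qtl = nrow(q),
               ve_single_mean = mean(q$variance_explained),
               ve_single_sd = if (nrow(q) > 1) sd(q$variance_explained) else 0,
               ve_all = veAll, stringsAsFactors = FALSE)
  })
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(), channel_or_group = character(),
               n_qtl = integer(), ve_single_mean = numeric(),
               ve_single_sd = numeric(), ve_all = numeric())
  out <- list(summary = summary)
  if (!is.null(truth) && nrow(truth)) {
    iv <- qtlIntervals(qtls, mk)
    hit <- vapply(seq_len(nrow(truth)), function(i) {
      any(iv$chrom == truth$chrom[i] & iv$start <= truth$end[i] &
            iv$end >= truth$start[i] & iv$trait == truth$trait[i])
    }, TRUE)
    called_hit <- if (nrow(iv)) vapply(seq_len(nrow(iv)), function(i) {
      any(truth$chrom == iv$chrom[i] & truth$start <= iv$end[i] &
            truth$end >= iv$start[i] & truth$trait == iv$trait[i])
    }, TRUE) else logical(0)
    out$recall <- mean(hit)
    out$precision <- if (length(called_hit)) mean(called_hit) else NA_real_
  }
  out
}

#' Genomic intervals of called QTLs
#'
#' @param qtls QTL result data.frame.
#' @param markers marker annotation (maps marker ids to coordinates).
#' @return data.frame (trait, channel_or_group, chrom, start, end).
#' @export
qtlIntervals <- function(qtls, markers) {
  s <- markers$start[match(qtls$start_marker, markers$marker_id)]
  e <- markers$end[match(qtls$end_marker, markers$marker_id)]
  data.frame(trait = qtls$trait, channel_or_group = qtls$channel_or_group,
             chrom = qtls$chrom, start = s, end = e,
             stringsAsFactors = FALSE)
}
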