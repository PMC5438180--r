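## End-to-end orchestration: config validation, staged execution,
## reproducibility manifest, summary report.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default: genome and generator
#' settings, caller thresholds (site filter 3, derivation distance 4
#' bins, top fraction 5\%, minimum 2 reads, score cutoffs 5/10/15), DMB
#' ratio boundaries 0.25/0.75, MNase ratio 2, TF fold 4, promoter 1 kb,
#' distal separation 3 sites, surface minimum distance 10 kb. Seeds are
#' mandatory and explicit; there is no time-based seeding.
#'
#' @return nested named list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    genome = list(nChroms = 5L, chromLength = 2e6, siteDensity = 4),
    tracks = list(),                     # overrides for .trackDefaults()
    truth = list(),                      # overrides for .truthDefaults()
    simulate = list(nPairs = 5e5, replicates = 3L, decayAlpha = 1.0,
                    interFrac = 0.2, loopFrac = 0.05, d0 = 1000,
                    telomereBias = 0.1, centromereBias = 0.3,
                    armBias = 0.3),
    caller = list(resolution = 250, minSites = 3L,
                  derivationDistance = 4L, topFraction = 0.05,
                  minReads = 2L, scoreCutoffs = c(5, 10, 15)),
    architecture = list(compartmentResolution = 1e5,
                        telomereBin = 2e4, telomereFlank = 2e5),
    enrichment = list(nPerm = 200L, highCutoff = 10,
                      dmbLowRatio = 0.25, dmbHighRatio = 0.75,
                      mnaseThreshold = 2),
    genes = list(promoterBp = 1000L, surfaceWindow = 5000,
                 surfaceMinDistance = 1e4, geneScoreCutoff = 5,
                 nRandomSets = 10L))
}

.validateConfig <- function(config) {
  cfg <- utils::modifyList(defaultConfig(), config)
  if (is.null(config$seed))
    stop("config must set an explicit seed", call. = FALSE)
  stopifnot(cfg$genome$nChroms >= 1, cfg$simulate$replicates >= 1)
  cfg
}

#' Read a pipeline config from YAML
#' @param path YAML file.
#' @return validated config list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path,
                               call. = FALSE)
  .validateConfig(yaml::read_yaml(path))
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Stages run in dependency order: simulate (genome, tracks, truth,
#' read pairs) -> filter/bin -> call and score -> architecture ->
#' enrichment -> gene statistics. Every output file is hashed into a
#' JSON manifest together with the config and seed; rerunning with an
#' identical config reproduces identical hashes.
#'
#' @param config config list (see \code{\link{defaultConfig}}) or a
#'   YAML path.
#' @param outdir output directory.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- .validateConfig(config)
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  wrote <- character()
  emit <- function(x, file) {
    path <- file.path(outdir, file)
    .writeTsv(x, path)
    wrote <<- c(wrote, file)
  }
  stage <- "simulate"
  res <- try({
    gn <- generateGenome(cfg$genome$nChroms, cfg$genome$chromLength,
                         cfg$genome$siteDensity, seed = cfg$seed)
    tb <- generateTracksAndFeatures(gn, cfg$tracks, seed = cfg$seed + 1L)
    truth <- buildTruth(gn, tb, cfg$truth, seed = cfg$seed + 2L)
    gts <- genotypeNames(truth)
    sim <- cfg$simulate
    pairsRaw <- list()
    for (g in gts) {
      reps <- lapply(seq_len(sim$replicates), function(r)
        simulateReadPairs(gn, truth, g, sim$nPairs,
                          decayAlpha = sim$decayAlpha,
                          interFrac = sim$interFrac,
                          loopFrac = sim$loopFrac, replicate = r,
                          seed = cfg$seed + 100L * match(g, gts),
                          d0 = sim$d0, telomereBias = sim$telomereBias,
                          centromereBias = sim$centromereBias,
                          armBias = sim$armBias))
      pairsRaw[[g]] <- combineReplicates(reps, gn)
    }
    fixMan <- writeFixture(file.path(outdir, "fixture"), gn, tb, truth,
                           pairsRaw)
    wrote <- c(wrote, file.path("fixture", fixMan$file))

    stage <- "bin"
    cal <- cfg$caller
    pairsF <- lapply(pairsRaw, filterPairsBySites, genome = gn,
                     minSites = cal$minSites)
    binned <- lapply(pairsF, binPairs, resolution = cal$resolution,
                     byReplicate = TRUE)
    for (g in gts)
      emit(decayCurve(pairsF[[g]], gn, resolution = cal$resolution),
           paste0("decay_", g, ".tsv"))

    stage <- "call"
    callsByG <- list()
    for (g in gts) {
      thr <- deriveCountThreshold(binned[[g]], cal$derivationDistance,
                                  cal$topFraction)
      cc <- callSimple(binned[[g]], thr, cal$derivationDistance,
                       cal$minReads, sample = g)
      cc <- scoreCalls(cc, totalReads = nrow(pairsF[[g]]))
      callsByG[[g]] <- cc
      emit(interactionCalls(cc), paste0("calls_", g, ".tsv"))
    }

    stage <- "architecture"
    arch <- cfg$architecture
    wtName <- truth@wildType
    m1 <- contactMatrix(pairsF[[wtName]], "chr1",
                        arch$compartmentResolution, gn)
    emit(compartmentEigenvector(m1), "compartment_chr1.tsv")
    hc <- filterByScore(callsByG[[wtName]], cfg$enrichment$highCutoff)
    emit(telomereMetaplot(hc, gn, arch$telomereBin, arch$telomereFlank),
         "telomere_metaplot.tsv")
    emit(centromereFractions(hc, gn), "centromere_fractions.tsv")

    stage <- "enrich"
    enr <- cfg$enrichment
    resbp <- cal$resolution
    state <- classifyChromatinState(getTrack(tb, "H3K4me2"),
                                    getTrack(tb, "H3K9me2"), resbp)
    control <- getTrack(tb, "control_coverage")
    ctab <- .trackTable(control, resbp)
    cenBins <- .grToBins(centromeres(gn), resbp)
    universe <- ctab[ctab$score >= 1 &
      !.binKey(ctab$chrom, ctab$bin) %in%
        .binKey(cenBins$chrom, cenBins$bin), c("chrom", "bin")]
    chhWt <- classifyMethylation(getTrack(tb,
      paste0("meCHH.", wtName)), methylationThresholds()["CHH"], resbp)
    mutName <- setdiff(gts, wtName)[1L]
    chhMut <- .trackTable(getTrack(tb, paste0("meCHH.", mutName)), resbp)
    dmb <- classifyDmbs(chhWt$level, chhMut$score,
                        chhWt$meth_class == "high",
                        enr$dmbLowRatio, enr$dmbHighRatio)
    dmbBins <- data.frame(chrom = chhWt$chrom, bin = chhWt$bin,
                          level = chhWt$level)[
                            !is.na(dmb) & dmb == "nrpe1_DMB", ]
    enrTab <- list()
    for (g in gts) {
      hcG <- filterByScore(callsByG[[g]], enr$highCutoff)
      e <- overlapEnrichment(hcG, dmbBins, universe, enr$nPerm,
                             seed = cfg$seed + 7L)
      enrTab[[g]] <- data.frame(genotype = g, observed = e$observed,
                                expected = e$expected, ratio = e$ratio)
    }
    emit(do.call(rbind, enrTab), "enrichment_dmb.tsv")
    dmrs <- mappabilityFilter(getFeature(tb, "DMR"), control)
    emit(dmrLoopCounts(callsByG, dmrs, cal$scoreCutoffs, wtName),
         "dmr_loop_counts.tsv")
    emit(data.frame(chrom = state$chrom, bin = state$bin,
                    state = state$chromatin_state),
         "chromatin_state.tsv")

    stage <- "genes"
    gcf <- cfg$genes
    genes <- geneTable(tb)
    proms <- definePromoters(genes, gn, gcf$promoterBp)
    groups <- expressionGroups(genes, wtName)
    emit(promoterInteractionStats(filterByScore(callsByG[[wtName]],
           enr$highCutoff), proms, groups), "promoter_group_stats.tsv")
    upGenes <- genes[genes$de_label == "up", , drop = FALSE]
    conn <- geneDmrConnections(callsByG, upGenes, genes, dmrs, gn,
                               gcf$geneScoreCutoff, wtName,
                               gcf$nRandomSets, seed = cfg$seed + 8L)
    emit(data.frame(genotype = names(conn$counts),
                    n_connected = as.numeric(conn$counts),
                    ratio_to_wt = as.numeric(conn$ratios),
                    random_ratio = as.numeric(
                      conn$randomRatios[names(conn$counts)])),
         "gene_dmr_connections.tsv")
    for (g in gts) {
      surf <- tssDmrSurface(callsByG[[g]], upGenes, dmrs, gn,
                            gcf$surfaceMinDistance, gcf$surfaceWindow,
                            seed = cfg$seed + 9L)
      emit(as.data.frame(surf$matrix), paste0("surface_", g, ".tsv"))
    }
    TRUE
  }, silent = TRUE)

  manifest <- list(config = cfg,
                   files = lapply(setNames(wrote, wrote), function(f) {
                     path <- file.path(outdir, f)
                     list(md5 = unname(tools::md5sum(path)),
                          rows = length(readLines(path, warn = FALSE)))
                   }))
  if (inherits(res, "try-error")) {
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline failed in stage '", stage, "': ",
         attr(res, "condition")$message, call. = FALSE)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Collects the stage outputs of \code{\link{runPipeline}} into a
#' one-page summary table; missing stage outputs are listed rather than
#' raising an error, and an empty call set is stated. Regeneration is
#' idempotent.
#'
#' @param outdir directory written by \code{\link{runPipeline}}.
#' @return data.frame summary (also written to report.tsv).
#' @export
pipelineReport <- function(outdir) {
  expect <- c("enrichment_dmb.tsv", "dmr_loop_counts.tsv",
              "gene_dmr_connections.tsv", "centromere_fractions.tsv")
  missing <- expect[!file.exists(file.path(outdir, expect))]
  rows <- list()
  note <- function(metric, value, detail = "")
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, value = value, detail = detail,
      stringsAsFactors = FALSE)
  if (length(missing)) {
    for (f in missing) note("missing_stage_output", NA_real_, f)
  }
  rd <- function(f) read.table(file.path(outdir, f), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  for (g in sub("^calls_(.*)\\.tsv$", "\\1",
                grep("^calls_.*\\.tsv$", list.files(outdir),
                     value = TRUE))) {
    cl <- rd(paste0("calls_", g, ".tsv"))
    if (nrow(cl) == 0) note("n_calls", 0, paste0(g, " (empty call set)"))
    else note("n_calls", nrow(cl), g)
  }
  if (!"enrichment_dmb.tsv" %in% missing) {
    e <- rd("enrichment_dmb.tsv")
    for (i in seq_len(nrow(e)))
      note("dmb_enrichment_ratio", e$ratio[i], e$genotype[i])
  }
  if (!"gene_dmr_connections.tsv" %in% missing) {
    e <- rd("gene_dmr_connections.tsv")
    for (i in seq_len(nrow(e)))
      note("gene_dmr_ratio", e$ratio_to_wt[i], e$genotype[i])
  }
  if (!"centromere_fractions.tsv" %in% missing) {
    e <- rd("centromere_fractions.tsv")
    note("centromere_inter_fraction",
         e$fraction[e$sample == "pooled"], "pooled")
  }
  out <- do.call(rbind, rows)
  .writeTsv(out, file.path(outdir, "report.tsv"))
  out
}
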