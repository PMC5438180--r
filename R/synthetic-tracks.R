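## Synthetic chromatin/methylation/expression tracks and feature sets.

.trackDefaults <- function() {
  list(
    genotypes = c("Col0", "nrpe1", "ago4"),
    wildType = "Col0",
    binSize = 250,
    nDmrs = 80,
    nOtherMeCHH = 60,
    nAgo4Peaks = 40,
    nTfs = 3,
    peaksPerTf = 40,
    nGenes = 400,
    geneLength = 2000,
    featureWidth = c(150, 450),
    bimodalGap = 4,          # separation of log2(H3K4me2/H3K9me2) modes
    activeFraction = 0.7,    # of non-centromeric bins
    chhLossRatio = 0.1,      # mutant/wild-type CHH at DMRs
    deUpFraction = 0.05,
    deDownFraction = 0.05,
    unmappableFraction = 0.02,
    mnaseReducedFraction = 0.5)
}

# Place n non-overlapping intervals avoiding `exclude`; error when the
# request exceeds genome capacity.
.placeIntervals <- function(genome, n, widthRange, exclude, maxTries = 50L) {
  if (n == 0L) return(GenomicRanges::GRanges())
  cs <- chromSizes(genome)
  placed <- GenomicRanges::GRanges()
  tries <- 0L
  while (length(placed) < n && tries < maxTries) {
    tries <- tries + 1L
    k <- (n - length(placed)) * 2L
    chrom <- sample(names(cs), k, replace = TRUE, prob = cs)
    w <- as.integer(round(runif(k, widthRange[1], widthRange[2])))
    start0 <- as.integer(floor(runif(k, 0, cs[chrom] - w)))
    cand <- .toGRanges(chrom, start0, start0 + w)
    keep <- !IRanges::overlapsAny(cand, exclude) &
      !IRanges::overlapsAny(cand, placed)
    cand <- cand[keep]
    if (length(cand)) {
      hits <- IRanges::findOverlaps(cand, cand)
      bad <- unique(S4Vectors::queryHits(hits)[
        S4Vectors::queryHits(hits) > S4Vectors::subjectHits(hits)])
      if (length(bad)) cand <- cand[-bad]
    }
    placed <- .cGR(placed, head(cand, n - length(placed)))
  }
  if (length(placed) < n)
    stop("could not place ", n, " non-overlapping features; ",
         "requested features exceed genome capacity", call. = FALSE)
  sort(placed)
}

.binGrid <- function(genome, binSize) {
  cs <- chromSizes(genome)
  unlist(GenomicRanges::tileGenome(cs, tilewidth = binSize))
}

#' Generate chromatin, methylation and expression tracks with feature sets
#'
#' Emulates the track inputs the enrichment and gene-looping analyses
#' consume: bimodal active/inactive chromatin (log2 H3K4me2/H3K9me2 drawn
#' from two Gaussian modes separated by \code{bimodalGap}), per-context
#' methylation fractions per genotype with a genotype-dependent CHH loss
#' at DMRs (mutant/wild-type ratio \code{chhLossRatio}), a
#' decrosslinked-control coverage track with a configurable unmappable
#' fraction, ChIP sample/control signal enriched at TF and AGO4 peaks, an
#' MNase wild-type/mutant ratio track, and a gene table with per-genotype
#' RPKM, differential-expression labels and log2 fold changes.
#'
#' @param genome a \linkS4class{HicGenome}.
#' @param config named list overriding generator defaults (feature counts,
#'   \code{bimodalGap}, \code{chhLossRatio}, ...).
#' @param seed integer seed.
#' @return a \linkS4class{TrackBundle}.
#' @export
generateTracksAndFeatures <- function(genome, config = list(), seed = 1L) {
  cfg <- utils::modifyList(.trackDefaults(), config)
  set.seed(as.integer(seed))
  cs <- chromSizes(genome)
  bins <- .binGrid(genome, cfg$binSize)
  nb <- length(bins)
  inCen <- IRanges::overlapsAny(bins, centromeres(genome))
  gts <- cfg$genotypes
  wt <- cfg$wildType
  muts <- setdiff(gts, wt)

  ## ---- features -----------------------------------------------------------
  avoid <- c(centromeres(genome), telomeres(genome))
  feats <- list()
  placedSoFar <- avoid
  wr <- cfg$featureWidth
  for (spec in list(c("DMR", cfg$nDmrs), c("otherMeCHH", cfg$nOtherMeCHH))) {
    gr <- .placeIntervals(genome, as.integer(spec[2]), wr, placedSoFar)
    feats[[spec[1]]] <- gr
    placedSoFar <- .cGR(placedSoFar, gr)
  }

  ## genes: bodies placed away from masks and methylated features
  geneGr <- .placeIntervals(genome, cfg$nGenes,
                            c(cfg$geneLength, cfg$geneLength), placedSoFar)
  placedSoFar <- .cGR(placedSoFar, geneGr)
  strand <- sample(c("+", "-"), cfg$nGenes, replace = TRUE)
  gstart0 <- GenomicRanges::start(geneGr) - 1L
  gend0 <- GenomicRanges::end(geneGr)
  tss <- ifelse(strand == "+", gstart0, gend0 - 1L)

  ## AGO4 peaks: some on DMRs (RdDM targets), some near gene promoters
  nOnDmr <- min(cfg$nAgo4Peaks %/% 2L, length(feats$DMR))
  ago4 <- feats$DMR[sample(length(feats$DMR), nOnDmr)]
  nProm <- cfg$nAgo4Peaks - nOnDmr
  gi <- sample(cfg$nGenes, min(nProm, cfg$nGenes))
  promStart <- ifelse(strand[gi] == "+", pmax(tss[gi] - 500L, 0L), tss[gi])
  ago4 <- sort(.cGR(ago4, .toGRanges(
    as.character(GenomicRanges::seqnames(geneGr))[gi],
    as.integer(promStart), as.integer(promStart) + 400L)))
  feats$AGO4 <- ago4
  for (tf in seq_len(cfg$nTfs)) {
    gr <- .placeIntervals(genome, cfg$peaksPerTf, wr, placedSoFar)
    feats[[paste0("TF", tf)]] <- gr
    placedSoFar <- .cGR(placedSoFar, gr)
  }

  ## ---- chromatin state tracks ---------------------------------------------
  active <- !inCen & runif(nb) < cfg$activeFraction
  mu <- cfg$bimodalGap / 2
  logRatio <- ifelse(active, rnorm(nb, mu, 0.5), rnorm(nb, -mu, 0.5))
  base <- rlnorm(nb, meanlog = 1, sdlog = 0.3)
  h3k4 <- base * 2^(logRatio / 2)
  h3k9 <- base * 2^(-logRatio / 2)

  ## ---- methylation tracks -------------------------------------------------
  hiCG <- inCen | runif(nb) < 0.15
  meCG_wt <- ifelse(hiCG, pmin(runif(nb, 0.75, 0.98), 1), runif(nb, 0, 0.08))
  meCHG_wt <- ifelse(hiCG, runif(nb, 0.35, 0.8), runif(nb, 0, 0.05))
  meCHH_wt <- ifelse(inCen, runif(nb, 0.12, 0.3), runif(nb, 0, 0.04))
  dmrBins <- IRanges::overlapsAny(bins, feats$DMR)
  otherBins <- IRanges::overlapsAny(bins, feats$otherMeCHH)
  meCHH_wt[dmrBins] <- runif(sum(dmrBins), 0.25, 0.6)
  meCHH_wt[otherBins] <- runif(sum(otherBins), 0.25, 0.6)

  meth <- list()
  for (g in gts) {
    cg <- meCG_wt; chg <- meCHG_wt; chh <- meCHH_wt
    if (g %in% muts) {
      chh[dmrBins] <- chh[dmrBins] * cfg$chhLossRatio
      chh[otherBins] <- chh[otherBins] * runif(sum(otherBins), 0.85, 1.0)
    }
    meth[[paste0("meCG.", g)]] <- cg
    meth[[paste0("meCHG.", g)]] <- chg
    meth[[paste0("meCHH.", g)]] <- pmin(pmax(chh, 0), 1)
  }

  ## ---- control coverage (mappability) -------------------------------------
  control <- rpois(nb, 5)
  unmap <- runif(nb) < cfg$unmappableFraction
  control[unmap] <- 0L
  featBins <- IRanges::overlapsAny(bins, Reduce(.cGR, feats))
  control[featBins & control == 0L] <- 1L   # features mappable by default

  ## ---- ChIP signal --------------------------------------------------------
  chipControl <- rpois(nb, 10) + 1
  enr <- rlnorm(nb, 0, 0.2)
  peakBins <- IRanges::overlapsAny(bins, .cGR(feats$AGO4, Reduce(
    .cGR, feats[grep("^TF", names(feats))])))
  enr[peakBins] <- runif(sum(peakBins), 4, 10)
  chipSample <- chipControl * enr

  ## ---- MNase ratio --------------------------------------------------------
  mnase <- rlnorm(nb, 0, 0.25)
  reduced <- sample(length(feats$DMR),
                    round(cfg$mnaseReducedFraction * length(feats$DMR)))
  redBins <- IRanges::overlapsAny(bins, feats$DMR[reduced])
  mnase[redBins] <- runif(sum(redBins), 2.5, 5)
  S4Vectors::mcols(feats$DMR)$mnase_reduced <-
    seq_along(feats$DMR) %in% reduced

  ## ---- gene expression ----------------------------------------------------
  nG <- cfg$nGenes
  rpkmWt <- rlnorm(nG, meanlog = 2, sdlog = 1.5)
  de <- rep("none", nG)
  nUp <- round(cfg$deUpFraction * nG)
  nDown <- round(cfg$deDownFraction * nG)
  idx <- sample(nG, nUp + nDown)
  de[idx[seq_len(nUp)]] <- "up"
  de[idx[nUp + seq_len(nDown)]] <- "down"
  log2fc <- rnorm(nG, 0, 0.2)
  log2fc[de == "up"] <- runif(nUp, 1, 3)
  log2fc[de == "down"] <- -runif(nDown, 1, 3)
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(nG)),
    chrom = as.character(GenomicRanges::seqnames(geneGr)),
    strand = strand, tss = as.integer(tss),
    start = gstart0, end = gend0,
    stringsAsFactors = FALSE)
  genes[[paste0("rpkm_", wt)]] <- rpkmWt
  for (g in muts)
    genes[[paste0("rpkm_", g)]] <- rpkmWt * 2^log2fc *
      rlnorm(nG, 0, 0.1)
  genes$de_label <- de
  genes$log2fc <- log2fc

  asTrack <- function(score) {
    gr <- bins
    S4Vectors::mcols(gr)$score <- as.numeric(score)
    gr
  }
  tracks <- c(
    lapply(meth, asTrack),
    list(H3K4me2 = asTrack(h3k4), H3K9me2 = asTrack(h3k9),
         control_coverage = asTrack(control),
         chip_sample = asTrack(chipSample),
         chip_control = asTrack(chipControl),
         mnase_ratio = asTrack(mnase)))
  methods::new("TrackBundle", tracks = tracks, features = feats,
               genes = genes, genotypes = gts)
}
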