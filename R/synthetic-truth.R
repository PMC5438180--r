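## Construction of the planted-loop ledger.

.truthDefaults <- function() {
  list(
    nExpressionLoops = 40,   # promoter <-> TF-peak loops, all genotypes
    nDmrLoops = 15,          # DMR <-> random distal loops, mutants only
    minLoopDistance = 2e4,
    maxLoopDistance = 1e6,
    wtRetention = 0.5,       # background contact retention at DMRs in WT
    rddmMultiplier = 1,      # mutant intensity at RdDM loops
    # optional locus-specific variation: a fraction of RdDM loops can
    # keep a weak wild-type presence instead of full suppression; the
    # default matches the model under test (no wild-type looping at
    # RdDM targets)
    wtRddmFraction = 0,
    wtRddmScale = 0.3,
    expressionMultiplier = 1)
}

#' Build the planted-loop truth ledger from generated tracks
#'
#' Encodes the model under test into the simulator: (i) expression loops
#' joining promoters of the most highly expressed genes to TF peaks, with
#' equal intensity in every genotype; (ii) RdDM loops joining promoters of
#' genes up-regulated in the mutants to DMRs, plus DMR-to-distal loops,
#' present only in the RdDM-mutant genotypes (wild-type multiplier 0); and
#' (iii) suppression of background contacts at DMR regions in wild-type
#' (retention \code{wtRetention}), so that RdDM targets are depleted of
#' contacts in wild-type and gain them in the mutants.
#'
#' @param genome a \linkS4class{HicGenome}.
#' @param tracks a \linkS4class{TrackBundle} from
#'   \code{\link{generateTracksAndFeatures}}.
#' @param config named list overriding \code{.truthDefaults()} entries.
#' @param seed integer seed.
#' @param extraSuppression optional \code{GRanges} of additional regions
#'   whose background contacts are thinned.
#' @param extraRetention numeric matrix (regions x genotypes) of retention
#'   probabilities for \code{extraSuppression}.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
buildTruth <- function(genome, tracks, config = list(), seed = 1L,
                       extraSuppression = NULL, extraRetention = NULL) {
  cfg <- utils::modifyList(.truthDefaults(), config)
  set.seed(as.integer(seed))
  gts <- genotypeNames(tracks)
  wt <- if ("Col0" %in% gts) "Col0" else gts[1L]
  muts <- setdiff(gts, wt)
  genes <- geneTable(tracks)
  cs <- chromSizes(genome)

  promoterOf <- function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      s <- max(g$tss - 1000L, 0L); e <- g$tss
    } else {
      s <- g$tss; e <- min(g$tss + 1000L, cs[[g$chrom]])
    }
    .toGRanges(g$chrom, as.integer(s), as.integer(e))
  }

  ## anchors accumulate as plain vectors; GRanges are built once at the
  ## end (repeated GRanges concatenation is quadratic)
  acc <- list(chromA = character(), sA = integer(), eA = integer(),
              chromB = character(), sB = integer(), eB = integer(),
              type = character())
  intensity <- NULL
  overlapsUsed <- function(chrom, s, e) {
    any((acc$chromA == chrom & s < acc$eA & acc$sA < e) |
        (acc$chromB == chrom & s < acc$eB & acc$sB < e))
  }
  addLoop <- function(a, b, type, inten) {
    ca <- as.character(GenomicRanges::seqnames(a))
    cb <- as.character(GenomicRanges::seqnames(b))
    sa <- GenomicRanges::start(a); ea <- GenomicRanges::end(a)
    sb <- GenomicRanges::start(b); eb <- GenomicRanges::end(b)
    if (overlapsUsed(ca, sa, ea) || overlapsUsed(cb, sb, eb) ||
        (ca == cb && sa <= eb && sb <= ea))
      return(FALSE)
    acc$chromA <<- c(acc$chromA, ca); acc$sA <<- c(acc$sA, sa)
    acc$eA <<- c(acc$eA, ea)
    acc$chromB <<- c(acc$chromB, cb); acc$sB <<- c(acc$sB, sb)
    acc$eB <<- c(acc$eB, eb)
    acc$type <<- c(acc$type, type)
    intensity <<- rbind(intensity, inten)
    TRUE
  }
  midOf <- function(gr)
    (GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2

  ## expression loops: top-RPKM gene promoters to same-chromosome TF
  ## peaks; genes whose promoter overlaps a methylated feature are
  ## skipped (methylated promoters are repressed, and such loops would
  ## leak expression signal into the RdDM-target statistics)
  tfPeaks <- Reduce(.cGR, tracks@features[grep("^TF",
                                            names(tracks@features))])
  methFeats <- .cGR(GenomicRanges::granges(tracks@features$DMR),
                    GenomicRanges::granges(tracks@features$otherMeCHH))
  rpkmWt <- genes[[paste0("rpkm_", wt)]]
  ord <- order(-rpkmWt, genes$gene_id)
  exprInt <- setNames(rep(cfg$expressionMultiplier, length(gts)), gts)
  planted <- 0L
  for (i in ord) {
    if (planted >= cfg$nExpressionLoops) break
    prom <- promoterOf(i)
    if (length(methFeats) && IRanges::overlapsAny(prom, methFeats))
      next
    onChr <- tfPeaks[as.character(GenomicRanges::seqnames(tfPeaks)) ==
                       genes$chrom[i]]
    if (!length(onChr)) next
    d <- abs(midOf(onChr) - midOf(prom))
    ok <- which(d >= cfg$minLoopDistance & d <= cfg$maxLoopDistance)
    if (!length(ok)) next
    peak <- onChr[sample(ok, 1L)]
    if (addLoop(prom, peak, "expression", exprInt))
      planted <- planted + 1L
  }

  ## RdDM loops: up-regulated gene promoters to DMRs, suppressed in
  ## wild-type (fully for most loops; a wtRddmFraction minority keeps a
  ## weak wild-type intensity, emulating locus-specific variation)
  rddmWtMult <- function() {
    if (runif(1) < cfg$wtRddmFraction)
      cfg$rddmMultiplier * cfg$wtRddmScale else 0
  }
  dmrs <- tracks@features$DMR
  usedDmr <- logical(length(dmrs))
  for (i in which(genes$de_label == "up")) {
    prom <- promoterOf(i)
    onChr <- which(!usedDmr &
      as.character(GenomicRanges::seqnames(dmrs)) == genes$chrom[i])
    if (!length(onChr)) next
    d <- abs(midOf(dmrs[onChr]) - midOf(prom))
    ok <- onChr[d >= cfg$minLoopDistance & d <= cfg$maxLoopDistance]
    if (!length(ok)) next
    j <- ok[sample(length(ok), 1L)]
    rddmInt <- setNames(rep(cfg$rddmMultiplier, length(gts)), gts)
    rddmInt[wt] <- rddmWtMult()
    if (addLoop(prom, dmrs[j], "rddm", rddmInt)) usedDmr[j] <- TRUE
  }

  ## remaining DMRs loop to random distal sites, mutants only
  freeDmr <- which(!usedDmr)
  nExtra <- min(cfg$nDmrLoops, length(freeDmr))
  if (nExtra > 0) {
    for (j in head(sample(freeDmr), nExtra)) {
      chrom <- as.character(GenomicRanges::seqnames(dmrs[j]))
      L <- cs[[chrom]]
      off <- sample(c(-1, 1), 1L) *
        round(runif(1, cfg$minLoopDistance, cfg$maxLoopDistance))
      s <- midOf(dmrs[j]) + off
      s <- max(min(s, L - 500), 0)
      rddmInt <- setNames(rep(cfg$rddmMultiplier, length(gts)), gts)
      rddmInt[wt] <- rddmWtMult()
      addLoop(dmrs[j], .toGRanges(chrom, as.integer(s),
                                  as.integer(s) + 400L), "rddm", rddmInt)
    }
  }

  ## suppression: background thinning at all DMRs in wild-type
  supp <- GenomicRanges::granges(dmrs)
  ret <- matrix(1, nrow = length(supp), ncol = length(gts),
                dimnames = list(NULL, gts))
  if (length(supp)) ret[, wt] <- cfg$wtRetention
  if (!is.null(extraSuppression) && length(extraSuppression)) {
    supp <- .cGR(supp, GenomicRanges::granges(extraSuppression))
    stopifnot(ncol(extraRetention) == length(gts))
    colnames(extraRetention) <- gts
    ret <- rbind(ret, extraRetention)
  }

  if (is.null(intensity))
    intensity <- matrix(numeric(), nrow = 0, ncol = length(gts))
  colnames(intensity) <- gts
  rownames(intensity) <- NULL
  anchorA <- if (length(acc$chromA))
    GenomicRanges::GRanges(acc$chromA,
                           IRanges::IRanges(acc$sA, acc$eA))
    else GenomicRanges::GRanges()
  anchorB <- if (length(acc$chromB))
    GenomicRanges::GRanges(acc$chromB,
                           IRanges::IRanges(acc$sB, acc$eB))
    else GenomicRanges::GRanges()
  loopType <- acc$type
  methods::new("SyntheticTruth", anchorA = anchorA, anchorB = anchorB,
               intensity = intensity, loopType = loopType,
               suppression = supp, retention = ret,
               genotypes = gts, wildType = wt)
}

#' Construct a SyntheticTruth directly from anchor coordinates
#'
#' Lower-level constructor used in tests and by users planting bespoke
#' structure: supply anchor intervals (0-based half-open) and a
#' loops-by-genotypes intensity matrix.
#'
#' @param anchorA,anchorB \code{GRanges} of loop anchors.
#' @param intensity numeric matrix loops x genotypes.
#' @param loopType character vector recycled to the number of loops.
#' @param genotypes genotype names (defaults to intensity colnames).
#' @param wildType wild-type genotype name.
#' @param suppression optional \code{GRanges} of thinned regions.
#' @param retention numeric matrix regions x genotypes.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
syntheticTruth <- function(anchorA, anchorB, intensity,
                           loopType = "planted",
                           genotypes = colnames(intensity),
                           wildType = genotypes[1L],
                           suppression = GenomicRanges::GRanges(),
                           retention = NULL) {
  intensity <- as.matrix(intensity)
  colnames(intensity) <- genotypes
  if (is.null(retention))
    retention <- matrix(1, nrow = length(suppression),
                        ncol = length(genotypes),
                        dimnames = list(NULL, genotypes))
  methods::new("SyntheticTruth", anchorA = anchorA, anchorB = anchorB,
               intensity = intensity,
               loopType = rep_len(loopType, length(anchorA)),
               suppression = suppression, retention = retention,
               genotypes = genotypes, wildType = wildType)
}
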