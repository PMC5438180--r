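# Shared synthetic fixture used across test files. Built once per run:
# a 3 x 1 Mb genome with the default three genotypes, two replicates of
# 1e5 read pairs each, filtered / binned / called / scored.

fixtureSeed <- 20240311L

.fx <- local({
  gn <- generateGenome(3, 1e6, siteDensity = 4, seed = fixtureSeed)
  tb <- generateTracksAndFeatures(
    gn, list(nGenes = 150, nDmrs = 30, nOtherMeCHH = 30),
    seed = fixtureSeed + 1L)
  truth <- buildTruth(gn, tb, seed = fixtureSeed + 2L)
  gts <- genotypeNames(truth)
  pairsRaw <- lapply(setNames(gts, gts), function(g)
    combineReplicates(lapply(1:2, function(r)
      simulateReadPairs(gn, truth, g, 1e5, replicate = r,
                        seed = fixtureSeed + 100L * match(g, gts),
                        telomereBias = 0.1, centromereBias = 0.3,
                        armBias = 0.3)), gn))
  pairsF <- lapply(pairsRaw, filterPairsBySites, genome = gn)
  binned <- lapply(pairsF, binPairs, resolution = 250,
                   byReplicate = TRUE)
  calls <- lapply(setNames(gts, gts), function(g) {
    thr <- deriveCountThreshold(binned[[g]])
    scoreCalls(callSimple(binned[[g]], thr, sample = g),
               totalReads = nrow(pairsF[[g]]))
  })
  list(genome = gn, tracks = tb, truth = truth, genotypes = gts,
       pairsRaw = pairsRaw, pairs = pairsF, binned = binned,
       calls = calls)
})

# quick constructor for a BinnedContacts from a plain count table
makeBinned <- function(df, resolution = 250) {
  df <- as.data.frame(df)
  methods::new("BinnedContacts", counts = df, resolution = resolution,
               nPairs = sum(df$count))
}

# quick constructor for an InteractionCalls object from a calls table
makeCalls <- function(df, resolution = 250, method = "simple",
                      sample = "test", settings = list()) {
  methods::new("InteractionCalls", calls = as.data.frame(df),
               resolution = resolution, method = method,
               sample = sample, settings = settings)
}

# single-chromosome bedGraph-style track from a score vector
mkTrack <- function(score, chrom = "chr1", binSize = 250) {
  n <- length(score)
  gr <- if (n == 0L) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = (seq_len(n) - 1L) * binSize + 1L,
                       width = binSize))
  S4Vectors::mcols(gr)$score <- score
  gr
}

# a hand-specified genome with known restriction sites, for boundary
# tests of site counting and distal classification
handGenome <- function(sites = list(chr1 = c(100L, 200L, 300L)),
                       len = 1e5L) {
  lens <- setNames(rep(as.integer(len), length(sites)), names(sites))
  cen <- GenomicRanges::GRanges(
    names(lens),
    IRanges::IRanges(start = as.integer(len * 0.45) + 1L,
                     end = as.integer(len * 0.55)))
  tel <- GenomicRanges::GRanges(
    rep(names(lens), each = 2),
    IRanges::IRanges(start = rep(c(1L, as.integer(len) - 999L),
                                 length(sites)),
                     end = rep(c(1000L, as.integer(len)),
                               length(sites))))
  methods::new("HicGenome", chromSizes = lens,
               restrictionSites = sites, centromeres = cen,
               telomeres = tel)
}
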