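# Bin classification, mappability filtering, permutation enrichment and
# replicate tests.

test_that("chromatin-state KDE split recovers a two-Gaussian mixture", {
  set.seed(61)
  n <- 4000
  truthActive <- runif(n) < 0.5
  lr <- ifelse(truthActive, rnorm(n, 2, 0.5), rnorm(n, -2, 0.5))
  base <- rlnorm(n, 1, 0.2)
  h3k4 <- mkTrack(base * 2^(lr / 2))
  h3k9 <- mkTrack(base * 2^(-lr / 2))
  st <- classifyChromatinState(h3k4, h3k9, 250, pseudocount = 0)
  acc <- mean((st$chromatin_state == "active") == truthActive)
  expect_gte(acc, 0.98)
  # all-zero repressive signal with pseudocount forces "active"
  stA <- classifyChromatinState(mkTrack(rep(4, 100)),
                                mkTrack(rep(0, 100)), 250)
  expect_true(all(stA$chromatin_state == "active"))
  expect_error(classifyChromatinState(mkTrack(numeric()),
                                      mkTrack(numeric())), "empty")
})

test_that("methylation classes use the >= boundary convention", {
  tr <- mkTrack(c(0.05, 0.1, 0.4, 0.79, 0.8, 1))
  cl <- classifyMethylation(tr, threshold = 0.8)
  expect_equal(cl$meth_class, c("low", "low", "low", "low",
                                "high", "high"))
  expect_true(all(classifyMethylation(tr, 0)$meth_class == "high"))
  expect_error(classifyMethylation(mkTrack(c(0.5, 1.2)), 0.5),
               "\\[0,1\\]")
  # bimodal mixture recovery
  set.seed(62)
  hi <- runif(2000) < 0.3
  lev <- ifelse(hi, runif(2000, 0.7, 1), runif(2000, 0, 0.3))
  cl2 <- classifyMethylation(mkTrack(lev), 0.5)
  expect_gte(mean((cl2$meth_class == "high") == hi), 0.99)
})

test_that("DMB classification reproduces the hand-evaluated ratio table", {
  # 20-bin worked table: ratios chosen to hit every branch (wild-type
  # level 0.5 keeps the boundary ratios exactly representable)
  wt <- rep(0.5, 20)
  ratio <- c(0.05, 0.1, 0.2, 0.24, 0.249,          # < 0.25 -> DMB
             0.25,                                  # boundary -> neither
             0.3, 0.5, 0.6, 0.7, 0.74,              # between -> neither
             0.75,                                  # boundary -> neither
             0.76, 0.8, 0.9, 1, 1.1, 1.5, 2, 3)     # > 0.75 -> other
  mut <- wt * ratio
  lab <- classifyDmbs(wt, mut, high = rep(TRUE, 20))
  expect_equal(lab[1:5], rep("nrpe1_DMB", 5))
  expect_equal(lab[6], "neither")
  expect_equal(lab[7:11], rep("neither", 5))
  expect_equal(lab[12], "neither")
  expect_equal(lab[13:20], rep("other_meCHH", 8))
  # direct rule evaluation on single worked values
  expect_equal(classifyDmbs(0.30, 0.03, TRUE), "nrpe1_DMB",
               ignore_attr = TRUE)
  expect_equal(classifyDmbs(0.30, 0.30, TRUE), "other_meCHH",
               ignore_attr = TRUE)
  expect_equal(classifyDmbs(0.30, 0.15, TRUE), "neither",
               ignore_attr = TRUE)
  # zero wild-type bins are excluded and counted
  lab0 <- classifyDmbs(c(0, 0.4), c(0, 0.1), high = c(TRUE, TRUE))
  expect_true(is.na(lab0[1]))
  expect_equal(attr(lab0, "n_excluded"), 1L)
  # non-high bins are not classified
  expect_true(is.na(classifyDmbs(0.4, 0.1, FALSE)[1]))
})

test_that("mappability filtering drops zero-coverage features", {
  feats <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 1001, 2001), width = 200))
  cov <- mkTrack(c(0, 5, 0, 0, 3, 0, 0, 0, 2, 1))
  out <- mappabilityFilter(feats, cov)
  expect_equal(length(out), 2L)
  expect_equal(attr(out, "n_removed"), 1L)
  allCov <- mkTrack(rep(2, 10))
  expect_equal(length(mappabilityFilter(feats, allCov)), 3L)
  expect_error(mappabilityFilter(feats, NULL), "control")
  # with a uniform control, filtered class coverage distributions match
  set.seed(63)
  covU <- mkTrack(stats::rpois(4000, 5))
  active <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(9e5, 50), width = 250))
  inactive <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(9e5, 50), width = 250))
  covOf <- function(f) {
    hits <- IRanges::findOverlaps(f, covU)
    tapply(S4Vectors::mcols(covU)$score[S4Vectors::subjectHits(hits)],
           S4Vectors::queryHits(hits), sum)
  }
  pv <- stats::wilcox.test(covOf(mappabilityFilter(active, covU)),
                           covOf(mappabilityFilter(inactive, covU)),
                           exact = FALSE)$p.value
  expect_gt(pv, 0.001)
})

test_that("overlap enrichment saturates at 1 and is null-calibrated", {
  cl <- .fx$calls$Col0
  res <- 250
  ct <- rddmHiC:::.trackTable(getTrack(.fx$tracks, "control_coverage"),
                              res)
  cen <- rddmHiC:::.grToBins(centromeres(.fx$genome), res)
  universe <- ct[ct$score >= 1 &
    !paste(ct$chrom, ct$bin) %in% paste(cen$chrom, cen$bin),
    c("chrom", "bin")]
  # features = entire universe: ratio is exactly 1
  e <- overlapEnrichment(cl, universe, universe, nPerm = 100, seed = 1)
  expect_equal(e$ratio, 1)
  expect_equal(e$expectedSd, 0)
  # random feature subsets: ratio close to 1
  set.seed(64)
  feat <- universe[sample.int(nrow(universe), 600), ]
  e2 <- overlapEnrichment(cl, feat, universe, nPerm = 300, seed = 2)
  expect_gt(e2$ratio, 0.85)
  expect_lt(e2$ratio, 1.15)
  # per-replicate ratios are reported for replicate-tagged calls
  expect_equal(nrow(e2$perReplicate), 2L)
  expect_error(overlapEnrichment(cl, universe[0, ], universe,
                                 nPerm = 100), "empty")
  # determinism under a fixed seed
  e3 <- overlapEnrichment(cl, feat, universe, nPerm = 300, seed = 2)
  expect_identical(e2$expected, e3$expected)
})

test_that("matched comparison trims both categories at the shared median", {
  set.seed(65)
  lev <- runif(400, 0.2, 0.6)
  dmb <- data.frame(chrom = "chr1", bin = seq_len(200), level = lev[1:200])
  oth <- data.frame(chrom = "chr1", bin = 200L + seq_len(200),
                    level = lev[201:400])
  universe <- data.frame(chrom = "chr1", bin = seq_len(2000))
  mc <- matchedComparison(.fx$calls$Col0, dmb, oth, universe,
                          mode = "low", nPerm = 100, seed = 1)
  # identical level distributions: matching keeps about half of each
  expect_lt(abs(mc$nDmb - 100), 3 * sqrt(100))
  expect_lt(abs(mc$nOther - 100), 3 * sqrt(100))
  # forced degenerate: all DMB levels below all other levels
  dmbLo <- transform(dmb, level = level / 10)
  expect_error(matchedComparison(.fx$calls$Col0, dmbLo, oth, universe,
                                 mode = "low", nPerm = 100),
               "other-meCHH subset empty")
})

test_that("the paired replicate t-test matches the closed form", {
  r <- replicateTtest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p.value, 1)
  expect_true(r$degenerate)
  r2 <- replicateTtest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r2$p.value, 0)
  expect_true(r2$degenerate)
  a <- c(1.3, 2.8, 2.1); b <- c(0.9, 1.7, 2.5)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(3))
  pref <- 2 * stats::pt(-abs(tstat), df = 2)
  r3 <- replicateTtest(a, b)
  expect_equal(r3$statistic, tstat, tolerance = 1e-12)
  expect_equal(r3$p.value, pref, tolerance = 1e-12)
  expect_error(replicateTtest(1, 2), ">= 2")
})

test_that("DMR loop counts are once-per-DMR with ratio bookkeeping", {
  dmrs <- getFeature(.fx$tracks, "DMR")
  same <- list(Col0 = .fx$calls$Col0, nrpe1 = .fx$calls$Col0)
  tab <- dmrLoopCounts(same, dmrs, cutoffs = c(5, 10),
                       wildType = "Col0")
  expect_true(all(tab$ratio_to_wt[tab$n_dmrs_with_call > 0] == 1))
  # a cutoff above every score leaves zero counts
  maxScore <- max(interactionCalls(.fx$calls$Col0)$score)
  hi <- dmrLoopCounts(same, dmrs, cutoffs = maxScore * 2,
                      wildType = "Col0")
  expect_true(all(hi$n_dmrs_with_call == 0))
  expect_true(all(is.na(hi$ratio_to_wt)))
  expect_error(dmrLoopCounts(same, dmrs, wildType = "zzz"),
               "wild-type")
})

test_that("nucleosome stratification uses a strict ratio threshold", {
  dmrs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 1001), width = 250))
  mnase <- mkTrack(c(2, 0.5, 0.8, 0.9, 2.5, 1))
  same <- list(Col0 = .fx$calls$Col0, ago4 = .fx$calls$Col0)
  tab <- nucleosomeStratifiedCounts(same, dmrs, mnase, threshold = 2)
  # ratio exactly 2 at the first DMR -> "not reduced" (strict >)
  expect_setequal(unique(tab$stratum), c("reduced", "not_reduced"))
  # threshold Inf: everything lands in "not reduced"
  tabInf <- nucleosomeStratifiedCounts(same, dmrs, mnase,
                                       threshold = Inf)
  expect_true(all(tabInf$stratum == "not_reduced"))
})
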