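# Gene-centred statistics: promoters, expression groups, TF connections,
# surfaces, DMR connections, AGO4 classes, upstream distances.

gnHand <- handGenome(list(chr1 = as.integer(seq(500, 99500, by = 500))))

geneRow <- function(id, chrom, strand, tss, rpkm = 1,
                    de = "none", lfc = 0) {
  df <- data.frame(gene_id = id, chrom = chrom, strand = strand,
                   tss = as.integer(tss),
                   start = as.integer(max(tss - 1000, 0)),
                   end = as.integer(tss + 2000),
                   stringsAsFactors = FALSE)
  df$rpkm_Col0 <- rpkm
  df$de_label <- de
  df$log2fc <- lfc
  df
}

test_that("promoters are 1 kb upstream, strand-aware and clipped", {
  genes <- rbind(geneRow("g1", "chr1", "+", 5000),
                 geneRow("g2", "chr1", "-", 5000),
                 geneRow("g3", "chr1", "+", 300))
  pr <- definePromoters(genes, gnHand)
  expect_equal(GenomicRanges::start(pr), c(4001L, 5001L, 1L))
  expect_equal(GenomicRanges::end(pr), c(5000L, 6000L, 300L))
  bad <- geneRow("g4", "chr1", "+", 2e5)
  expect_error(definePromoters(bad, gnHand), "outside")
})

test_that("expression groups are sized and tie-broken deterministically", {
  genes <- do.call(rbind, lapply(1:100, function(i)
    geneRow(sprintf("g%03d", i), "chr1", "+", i * 900,
            rpkm = c(rep(1, 50), 51:100)[i])))
  gr <- expressionGroups(genes, "Col0", fraction = 0.05)
  expect_equal(lengths(gr[c("inactive", "middle", "active")]),
               c(inactive = 5L, middle = 5L, active = 5L))
  expect_equal(gr$active, sprintf("g%03d", 96:100))
  # ties resolved by gene id: repeated calls identical
  gr2 <- expressionGroups(genes, "Col0", fraction = 0.05)
  expect_identical(gr, gr2)
  expect_error(expressionGroups(genes[1:5, ], "Col0", 0.05), "fraction")
})

test_that("promoter interaction shares sum to 100% and detect loading", {
  genes <- do.call(rbind, lapply(1:20, function(i)
    geneRow(sprintf("g%02d", i), "chr1", "+", i * 4000, rpkm = i)))
  pr <- definePromoters(genes, gnHand)
  # all calls anchored on gene g20's promoter bins (tss 80000)
  calls <- makeCalls(data.frame(
    chromA = "chr1", binA = (80000 - 500) %/% 250,
    chromB = "chr1", binB = 300L, count = 3L, score = 30))
  groups <- list(lo = sprintf("g%02d", 1:5),
                 hi = sprintf("g%02d", 16:20))
  st <- promoterInteractionStats(calls, pr, groups)
  expect_equal(st$share_pct[st$group == "hi"], 100)
  expect_equal(st$share_pct[st$group == "lo"], 0)
  # shares over a full partition sum to 100
  part <- split(genes$gene_id, rep(1:4, each = 5))
  st2 <- promoterInteractionStats(calls, pr, part)
  expect_equal(sum(st2$share_pct), 100)
  expect_equal(sum(st2$expected_pct), 100)
})

test_that("interaction-level expression grouping follows the coupling", {
  set.seed(71)
  nG <- 150
  gnWide <- handGenome(list(chr1 = as.integer(seq(500, 299500, 500))),
                       len = 3e5L)
  # promoters spaced well apart so no bin serves two genes
  genes <- do.call(rbind, lapply(seq_len(nG), function(i)
    geneRow(sprintf("g%03d", i), "chr1", "+", i * 1500 + 2000,
            rpkm = rlnorm(1, 2, 1))))
  pr <- definePromoters(genes, gnWide)
  # scores proportional to RPKM, anchored mid-promoter
  promBin <- (genes$tss - 600) %/% 250
  calls <- makeCalls(data.frame(
    chromA = "chr1", binA = promBin, chromB = "chr1",
    binB = promBin + 100L, count = 3L,
    score = 5 + genes$rpkm_Col0 * 2))
  r <- expressionByInteractionLevel(calls, pr, genes, "Col0",
                                    fraction = 0.1)
  expect_gt(median(r$rpkm$highest), median(r$rpkm$lowest))
  expect_lt(r$p[["highest_vs_lowest"]], 0.01)
})

test_that("TF connection analysis ties expression to wired peaks", {
  set.seed(72)
  genes <- do.call(rbind, lapply(1:30, function(i)
    geneRow(sprintf("g%02d", i), "chr1", "+", i * 3000,
            rpkm = ifelse(i <= 10, 100, 1))))
  pr <- definePromoters(genes, gnHand)
  # peaks at bins looped to the promoters of the 10 high-RPKM genes
  peakBin <- 350L + seq_len(10)
  calls <- makeCalls(data.frame(
    chromA = "chr1", binA = (genes$tss[1:10] - 500) %/% 250,
    chromB = "chr1", binB = peakBin, count = 2L, score = 20))
  tf <- list(TFa = GenomicRanges::GRanges("chr1",
    IRanges::IRanges(peakBin * 250 + 1L, width = 250)))
  out <- tfConnectedExpression(calls, tf, pr, genes, "Col0")
  expect_equal(out$n_connected, 10L)
  expect_gt(out$median_connected, out$median_unconnected)
  expect_gt(out$median_connected, attr(out, "genome_median"))
  # empty peak set is skipped with a warning
  expect_warning(
    out2 <- tfConnectedExpression(calls,
      c(tf, list(TFb = GenomicRanges::GRanges())), pr, genes, "Col0"),
    "zero peaks")
  expect_equal(nrow(out2), 1L)
  # a single connected gene contributes its own RPKM as the median
  one <- makeCalls(data.frame(
    chromA = "chr1", binA = (genes$tss[3] - 500) %/% 250,
    chromB = "chr1", binB = peakBin[1], count = 2L, score = 20))
  o1 <- tfConnectedExpression(one, tf, pr, genes, "Col0")
  expect_equal(o1$median_connected, genes$rpkm_Col0[3])
})

test_that("distal ChIP enrichment separates up and down gene sets", {
  genes <- rbind(geneRow("up1", "chr1", "+", 20000, de = "up"),
                 geneRow("dn1", "chr1", "+", 60000, de = "down"))
  pr <- definePromoters(genes, gnHand)
  # distal ends: bin 200 loops to up1, bin 300 loops to dn1
  calls <- makeCalls(data.frame(
    chromA = "chr1", binA = c((20000 - 500) %/% 250,
                              (60000 - 500) %/% 250),
    chromB = "chr1", binB = c(200L, 300L), count = 3L,
    score = c(20, 20)))
  n <- 400
  ctrl <- mkTrack(rep(10, n))
  samp <- rep(10, n)
  samp[301] <- 10 * 8     # strong peak only at the down-gene distal end
  chip <- mkTrack(samp)
  r <- distalChipEnrichment(calls, pr,
                            list(up = "up1", down = "dn1"),
                            chip, ctrl, scoreCutoff = 15,
                            foldThreshold = 4)
  expect_gt(r$down, r$up)
  expect_equal(r$bound_down, 1)
  expect_equal(r$bound_up, 0)
  # a region at exactly four-fold counts as bound (>= rule)
  samp4 <- rep(10, n)
  samp4[301] <- (10 + 0.5) * 4 - 0.5   # exactly 4x after pseudocounts
  r4 <- distalChipEnrichment(calls, pr,
                             list(up = "up1", down = "dn1"),
                             mkTrack(samp4), ctrl, scoreCutoff = 15)
  expect_equal(r4$bound_down, 1)
  expect_error(distalChipEnrichment(calls, pr,
                                    list(up = "zz", down = "yy"),
                                    chip, ctrl, scoreCutoff = 1e9),
               "no qualifying")
})

test_that("gene-DMR connections ratio to wild-type with empty-DMR flagging", {
  genes <- do.call(rbind, lapply(1:10, function(i)
    geneRow(sprintf("g%02d", i), "chr1", "+", i * 8000, de = "up")))
  dmrs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(90001, 90400))
  calls <- makeCalls(data.frame(
    chromA = "chr1", binA = (genes$tss[1:4] - 500) %/% 250,
    chromB = "chr1", binB = 360L, count = 3L, score = 20),
    sample = "x")
  same <- list(Col0 = calls, ago4 = calls)
  out <- geneDmrConnections(same, genes, genes, dmrs, gnHand,
                            scoreCutoff = 5, nRandomSets = 10,
                            seed = 3)
  expect_equal(unname(out$counts), c(4, 4))
  expect_equal(unname(out$ratios), c(1, 1))
  expect_false(out$wildTypeUndefined)
  # empty DMR set: zero counts and undefined ratios
  out0 <- geneDmrConnections(same, genes, genes,
                             GenomicRanges::GRanges(), gnHand,
                             nRandomSets = 10, seed = 3)
  expect_equal(unname(out0$counts), c(0, 0))
  expect_true(out0$wildTypeUndefined)
})

test_that("fold-change splits compare connected vs unconnected genes", {
  set.seed(73)
  lfc <- c(runif(50, 0.5, 2), -runif(50, 0.5, 2))
  connected <- rep(c(TRUE, FALSE), 50)
  r <- deDirectionSplit(connected, lfc)
  expect_true(all(c("positive", "negative") %in% names(r)))
  expect_true(is.numeric(r$positive$p))
  # all genes connected: stratum comparison skipped with a warning
  expect_warning(r2 <- deDirectionSplit(rep(TRUE, 100), lfc),
                 "empty group")
  expect_true(is.na(r2$positive$p))
})

test_that("AGO4 localization respects the 3-site distal rule", {
  # restriction sites every 500 bp -> distance in sites is distance/500
  genes <- geneRow("g1", "chr1", "+", 20000)
  ago4Prom <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(19500, 19900))     # inside the promoter
  # distal call ends: one 2 sites from the gene region, one far away
  nearBin <- (genes$end + 800) %/% 250     # ~2 sites away
  farBin <- (genes$end + 30000) %/% 250    # ~60 sites away
  mkc <- function(distBin) makeCalls(data.frame(
    chromA = "chr1", binA = (20000 - 500) %/% 250, chromB = "chr1",
    binB = distBin, count = 3L, score = 20))
  ago4Far <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(farBin * 250 + 1L, width = 250))
  # AGO4 only at the promoter
  r1 <- ago4LocalizationClasses(mkc(farBin), genes, ago4Prom, gnHand)
  expect_equal(unname(r1$counts["promoter_only"]), 1L)
  # AGO4 at a qualifying distal end only
  r2 <- ago4LocalizationClasses(mkc(farBin), genes, ago4Far, gnHand)
  expect_equal(unname(r2$counts["distal_only"]), 1L)
  # AGO4 at both ends
  r3 <- ago4LocalizationClasses(mkc(farBin), genes,
                                c(ago4Prom, ago4Far), gnHand)
  expect_equal(unname(r3$counts["both"]), 1L)
  # a 2-site separation does not qualify as distal
  ago4Near <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(nearBin * 250 + 1L, width = 250))
  r4 <- ago4LocalizationClasses(mkc(nearBin), genes, ago4Near, gnHand)
  expect_equal(unname(r4$counts["distal_only"]), 0L)
})

test_that("upstream peak distances are strand-aware with censoring", {
  genes <- rbind(geneRow("g1", "chr1", "+", 10000),
                 geneRow("g2", "chr1", "-", 50000),
                 geneRow("g3", "chr1", "+", 200))
  # peak abutting g1's TSS (0-based [9500,10000)), one 3 kb beyond g2
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(9501, 53001), c(10000, 53400)))
  r <- upstreamPeakDistances(genes, peaks, cutoff = 2500)
  expect_equal(unname(r$distances["g1"]), 0)
  # gap between the minus-strand TSS base and the peak edge: positions
  # 50001..52999 lie between them
  expect_equal(unname(r$distances["g2"]), 2999)
  expect_true(is.na(r$distances["g3"]))
  expect_equal(r$n_censored, 1L)
  expect_equal(r$fraction_within, 1 / 3)
  # all peaks beyond the cutoff
  far <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1001, 1400))
  r2 <- upstreamPeakDistances(genes[1, ], far, cutoff = 2500)
  expect_equal(r2$fraction_within, 0)
  # exponential-spacing sanity: mean nearest distance ~ 1/density
  set.seed(74)
  dens <- 1 / 2000
  pk <- sort(sample.int(1e5 - 400, 50))
  pkGr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(pk + 1L, width = 10))
  gtab <- do.call(rbind, lapply(1:200, function(i)
    geneRow(sprintf("g%03d", i), "chr1", "+",
            sample.int(9e4, 1) + 5000)))
  r3 <- upstreamPeakDistances(gtab, pkGr)
  m <- mean(r3$distances, na.rm = TRUE)
  expect_gt(m, 0.4 / dens * 0.5)
  expect_lt(m, 1 / dens * 2)
})

test_that("DMR orientation uses transcription-relative signs", {
  genes <- geneRow("g1", "chr1", "-", 50000)
  # DMR 20 kb downstream of a minus-strand TSS (i.e. at lower coords)
  dmrs <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(30001, 30250))
  calls <- makeCalls(data.frame(
    chromA = "chr1", binA = 30000 %/% 250, chromB = "chr1",
    binB = 50000 %/% 250, count = 3L, score = 10))
  r <- dmrGeneDistanceOrientation(calls, genes, dmrs, gnHand)
  expect_equal(nrow(r$table), 1L)
  expect_lt(r$table$signed_distance, 0)       # downstream -> negative
  expect_equal(r$table$orientation, "downstream")
  expect_equal(r$table$distance_bp, 50000 - (30000 %/% 250 * 250 + 125))
  # symmetric plant: upstream fraction near one half
  set.seed(75)
  offs <- sample(c(-1, 1), 60, TRUE) * 20000
  g2 <- do.call(rbind, lapply(1:60, function(i)
    geneRow(sprintf("s%02d", i), "chr1", "+", 50000)))
  g2$gene_id <- sprintf("s%02d", 1:60)
  # distinct TSSs to keep promoters apart
  g2$tss <- as.integer(seq(30000, 70000, length.out = 60))
  g2$start <- g2$tss - 1000L; g2$end <- g2$tss + 2000L
  dmrPos <- g2$tss + offs
  d2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(dmrPos + 1L, width = 250))
  c2 <- makeCalls(data.frame(
    chromA = "chr1",
    binA = pmin((g2$tss - 500) %/% 250, dmrPos %/% 250),
    chromB = "chr1",
    binB = pmax((g2$tss - 500) %/% 250, dmrPos %/% 250),
    count = 3L, score = 10))
  r2 <- dmrGeneDistanceOrientation(c2, g2, d2, gnHand)
  expect_gt(r2$upstream_fraction, 0.25)
  expect_lt(r2$upstream_fraction, 0.75)
})
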