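# Hi-C core: site counting, site filtering, binning, decay, matrices,
# replicate correlation and pooling.

test_that("sitesBetween counts sites strictly inside the interval", {
  map <- list(chr1 = c(100L, 200L, 300L))
  expect_equal(sitesBetween(map, "chr1", 50, 350), 3L)
  expect_equal(sitesBetween(map, "chr1", 150, 250), 1L)
  expect_equal(sitesBetween(map, "chr1", 200, 200), 0L)
  # symmetry and endpoint exclusion
  expect_equal(sitesBetween(map, "chr1", 350, 50), 3L)
  expect_equal(sitesBetween(map, "chr1", 100, 300), 1L)
  expect_error(sitesBetween(map, "chrX", 0, 10), "unknown chromosome")
})

test_that("sitesBetween agrees with a brute-force scan on random maps", {
  set.seed(91)
  for (rep in 1:25) {
    sites <- sort(sample.int(1e5, 200))
    map <- list(chr1 = sites)
    a <- sample.int(1e5, 50)
    b <- sample.int(1e5, 50)
    brute <- vapply(seq_along(a), function(i) {
      lo <- min(a[i], b[i]); hi <- max(a[i], b[i])
      sum(sites > lo & sites < hi)
    }, numeric(1))
    expect_identical(sitesBetween(map, "chr1", a, b), as.integer(brute))
  }
})

test_that("the site filter drops close pairs and exempts inter pairs", {
  gn <- handGenome(list(chr1 = c(100L, 200L, 300L, 400L, 500L),
                        chr2 = c(1000L)))
  mk <- function(chromA, posA, chromB, posB)
    data.frame(chromA = chromA, posA = posA, strandA = "+",
               chromB = chromB, posB = posB, strandB = "+",
               replicate = 1L)
  pairs <- rbind(
    mk("chr1", 110, "chr1", 190),   # 0 sites between -> removed
    mk("chr1", 50, "chr1", 350),    # exactly 3 sites -> removed (strict >)
    mk("chr1", 50, "chr1", 450),    # 4 sites -> kept
    mk("chr1", 10, "chr2", 10))     # inter-chromosomal -> kept
  out <- filterPairsBySites(pairs, gn, minSites = 3)
  expect_equal(nrow(out), 2L)
  expect_true(any(out$chromB == "chr2"))
  expect_true(any(out$posB == 450))
})

test_that("binning follows the half-open floor convention and conserves counts", {
  mk <- function(posA, posB)
    data.frame(chromA = "chr1", posA = posA, strandA = "+",
               chromB = "chr1", posB = posB, strandB = "+",
               replicate = 1L)
  p <- rbind(mk(0, 5000), mk(250, 5000))
  b <- contactCounts(binPairs(p, 250))
  expect_equal(sort(b$binA), c(0L, 1L))
  p10 <- do.call(rbind, replicate(10, mk(100, 9000), simplify = FALSE))
  b10 <- contactCounts(binPairs(p10, 250))
  expect_equal(nrow(b10), 1L)
  expect_equal(b10$count, 10L)
  # conservation on the shared fixture
  b <- binPairs(.fx$pairs$Col0, 250)
  expect_equal(sum(contactCounts(b)$count), nrow(.fx$pairs$Col0))
})

test_that("decay curve conserves counts and flattens for shuffled input", {
  one <- data.frame(chromA = "chr1", posA = 1000L, strandA = "+",
                    chromB = "chr1", posB = 2000L, strandB = "+",
                    replicate = 1L)
  dc <- decayCurve(one, resolution = 250)
  expect_equal(dc$count[dc$distance == 1000], 1L)
  dc2 <- decayCurve(.fx$pairs$nrpe1, resolution = 250)
  nIntra <- sum(.fx$pairs$nrpe1$chromA == .fx$pairs$nrpe1$chromB)
  expect_equal(sum(dc2$count), nIntra)
  # uniform (no-decay) positions give a near-zero slope well below the
  # chromosome length
  set.seed(5)
  n <- 2e5
  pos <- matrix(sample.int(1e6, 2 * n, replace = TRUE), ncol = 2)
  unif <- data.frame(chromA = "chr1", posA = pmin(pos[, 1], pos[, 2]),
                     strandA = "+", chromB = "chr1",
                     posB = pmax(pos[, 1], pos[, 2]), strandB = "+",
                     replicate = 1L)
  sl <- fitDecaySlope(decayCurve(unif, resolution = 250),
                      range = c(2e4, 5e4))
  expect_lt(abs(sl), 0.15)
})

test_that("fragment assignment moves reads to fragment midpoints", {
  gn <- handGenome(list(chr1 = c(1000L, 2000L, 3000L)), len = 4000L)
  p <- data.frame(chromA = "chr1", posA = 10L, strandA = "+",
                  chromB = "chr1", posB = 2999L, strandB = "+",
                  replicate = 1L)
  dc <- decayCurve(p, gn, resolution = 250, fragmentAssign = TRUE)
  # fragments [0,1000) and [2000,3000): midpoints 500 and 2500
  expect_equal(dc$distance, (2500 - 500) %/% 250 * 250)
})

test_that("contact matrices are symmetric and conserve mass", {
  m <- contactMatrix(.fx$pairs$Col0, "chr1", 1e5, .fx$genome)
  expect_true(isSymmetric(unname(m)))
  p1 <- .fx$pairs$Col0[.fx$pairs$Col0$chromA == "chr1" &
                         .fx$pairs$Col0$chromB == "chr1", ]
  expect_equal(sum(m[upper.tri(m)]) + sum(diag(m)), nrow(p1))
  # rebinning conserves the total
  b250 <- binPairs(p1, 250)
  m2 <- contactMatrix(b250, "chr1", 1e5, .fx$genome)
  expect_equal(sum(m2), sum(m))
  expect_error(contactMatrix(b250, "chr1", 375, .fx$genome),
               "does not divide")
})

test_that("replicate correlation is depth-normalized and bounded", {
  b1 <- binPairs(.fx$pairsRaw$Col0[.fx$pairsRaw$Col0$replicate == 1L],
                 25000)
  b2 <- binPairs(.fx$pairsRaw$Col0[.fx$pairsRaw$Col0$replicate == 2L],
                 25000)
  r <- replicateCorrelation(b1, b2)
  # replicates share all planted and background structure, so they
  # correlate strongly (contrast with the |r| < 0.1 independence bound)
  expect_gt(r, 0.8)
  expect_lte(r, 1)
  expect_equal(replicateCorrelation(b1, b1), 1)
  # doubling depth leaves the correlation at 1
  dbl <- contactCounts(b1)
  dbl$count <- dbl$count * 2L
  expect_equal(replicateCorrelation(b1, makeBinned(dbl, 25000)), 1)
  # independent uniform samples decorrelate
  set.seed(6)
  rnd <- function(s) {
    set.seed(s)
    df <- data.frame(chromA = "chr1",
                     binA = sample.int(200, 3e4, replace = TRUE) - 1L,
                     chromB = "chr1",
                     binB = sample.int(200, 3e4, replace = TRUE) - 1L)
    df <- rddmHiC:::.canonicalizeBins(df)
    dt <- data.table::as.data.table(df)[, list(count = .N),
      by = c("chromA", "binA", "chromB", "binB")]
    makeBinned(as.data.frame(dt), 25000)
  }
  expect_lt(abs(replicateCorrelation(rnd(1), rnd(2))), 0.1)
  # zero-variance input is an error
  flat <- makeBinned(data.frame(chromA = "chr1", binA = 0:9,
                                chromB = "chr1", binB = 10:19,
                                count = rep(1L, 10)), 25000)
  expect_error(replicateCorrelation(flat, flat), "zero-variance")
})

test_that("pooling replicates preserves counts and commutes with binning", {
  one <- .fx$pairsRaw$Col0[.fx$pairsRaw$Col0$replicate == 1L]
  expect_equal(nrow(combineReplicates(list(one))), nrow(one))
  three <- combineReplicates(list(one, one, one))
  expect_equal(nrow(three), 3L * nrow(one))
  # pooling then binning equals binning then summing
  two <- .fx$pairsRaw$Col0[.fx$pairsRaw$Col0$replicate == 2L]
  pooled <- contactCounts(binPairs(combineReplicates(list(one, two)),
                                   250))
  k <- function(d) paste(d$chromA, d$binA, d$chromB, d$binB)
  b1 <- contactCounts(binPairs(one, 250))
  b2 <- contactCounts(binPairs(two, 250))
  agg <- rowsum(c(b1$count, b2$count), c(k(b1), k(b2)))
  expect_equal(sort(pooled$count), sort(unname(agg[, 1])))
  expect_error(combineReplicates(list(one), handGenome()),
               "genome mismatch")
})

test_that("loadPairs validates, canonicalizes and counts malformed rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chromA\tposA\tstrandA\tchromB\tposB\tstrandB\treplicate",
               "chr2\t500\t+\tchr1\t100\t-\t1",
               "chr1\t-5\t+\tchr1\t900\t+\t1",
               paste(rep(c("chr1\t10\t+\tchr1\t800\t+\t1"), 200),
                     collapse = "\n")), f)
  p <- loadPairs(f, handGenome(list(chr1 = c(50L), chr2 = c(60L))))
  expect_equal(attr(p, "n_malformed"), 1L)
  expect_equal(p$chromA[1], "chr1")   # canonicalized swap
  expect_equal(p$posA[1], 100L)
  # empty file warns and returns an empty stream
  f2 <- tempfile(); writeLines(character(), f2)
  expect_warning(p2 <- loadPairs(f2), "empty")
  expect_equal(nrow(p2), 0L)
  # > 1% malformed rows is a hard error
  f3 <- tempfile()
  writeLines(c("chromA\tposA\tstrandA\tchromB\tposB\tstrandB\treplicate",
               "chr1\t-1\t+\tchr1\t10\t+\t1",
               "chr1\t5\t+\tchr1\t10\t+\t1"), f3)
  expect_error(loadPairs(f3), "malformed")
  # unknown chromosome names the offender
  expect_error(loadPairs(f, handGenome(list(chr1 = c(50L)))), "chr2")
  unlink(c(f, f2, f3))
})
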