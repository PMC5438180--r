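## Stringent caller: ICE matrix balancing, distance-stratified expected
## counts, upper-tail count test, permutation-based FDR cutoff.

#' Iterative correction (ICE) of a contact matrix
#'
#' Balances a symmetric nonnegative contact matrix so that every
#' unmasked row sums to the same total, by iteratively dividing rows and
#' columns by their relative marginals. Rows with zero mass are masked.
#' The original matrix equals the balanced matrix scaled by the outer
#' product of the returned biases.
#'
#' @param m symmetric nonnegative matrix.
#' @param tol relative row-sum tolerance for convergence.
#' @param maxIter iteration cap; non-convergence is an error reporting
#'   the residual.
#' @return list with \code{matrix} (balanced), \code{bias} (per-row,
#'   NA for masked rows) and \code{mask} (logical, TRUE = usable row).
#' @export
iceNormalize <- function(m, tol = 1e-5, maxIter = 200L) {
  if (!isSymmetric(unname(m)))
    stop("matrix must be symmetric", call. = FALSE)
  if (any(m < 0)) stop("matrix must be nonnegative", call. = FALSE)
  mask <- rowSums(m) > 0
  if (!any(mask)) stop("all-zero matrix cannot be balanced", call. = FALSE)
  w <- m[mask, mask, drop = FALSE]
  bias <- rep(1, nrow(w))
  for (it in seq_len(maxIter)) {
    s <- rowSums(w)
    db <- s / mean(s)
    db[db == 0] <- 1
    w <- w / outer(db, db)
    bias <- bias * db
    s2 <- rowSums(w)
    resid <- max(abs(s2 / mean(s2) - 1))
    if (resid < tol) {
      out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
      out[mask, mask] <- w
      fullBias <- rep(NA_real_, nrow(m))
      fullBias[mask] <- bias
      return(list(matrix = out, bias = fullBias, mask = mask,
                  iterations = it))
    }
  }
  stop(sprintf("ICE did not converge in %d iterations (residual %.3g)",
               maxIter, resid), call. = FALSE)
}

#' Stringent intra-chromosomal interaction calling
#'
#' Bins intra-chromosomal pairs at \code{resolution} (default 1 kb),
#' balances each chromosome's contact matrix with ICE, estimates the
#' expected contact count per distance stratum from the ICE-corrected
#' counts pooled genome-wide (strata with fewer than
#' \code{minStratumPairs} occupied bin pairs are merged with neighbours,
#' then smoothed across distance), and tests each observed bin pair more
#' than \code{minDistance} bp apart with an upper-tail Poisson test
#' against its bias-scaled expectation. This is a distance-stratified
#' simplification of spline-based callers, validated by null calibration
#' rather than output identity.
#'
#' @param pairs pairs table (site-filtered).
#' @param genome a \linkS4class{HicGenome}.
#' @param resolution bin width in bp.
#' @param minDistance minimum separation in bp (strict >).
#' @param minStratumPairs minimum occupied bin pairs per distance
#'   stratum before merging.
#' @param sample sample label.
#' @return an \linkS4class{InteractionCalls} with method "stringent";
#'   calls carry observed/expected counts and p-values.
#' @export
callStringent <- function(pairs, genome, resolution = 1000,
                          minDistance = 3000, minStratumPairs = 50L,
                          sample = "sample") {
  pairs <- data.table::as.data.table(pairs)
  intra <- pairs[.isIntra(pairs)]
  if (nrow(intra) == 0L)
    stop("no intra-chromosomal pairs available", call. = FALSE)
  cs <- chromSizes(genome)
  minBins <- as.integer(floor(minDistance / resolution)) + 1L

  tested <- list()
  for (chrom in intersect(names(cs), unique(intra$chromA))) {
    p <- intra[intra$chromA == chrom]
    m <- contactMatrix(p, chrom, resolution, genome)
    ice <- iceNormalize(m, tol = 1e-4, maxIter = 300L)
    bias <- ice$bias
    dt <- data.table::data.table(
      binA = .binIndex(p$posA, resolution),
      binB = .binIndex(p$posB, resolution))
    swap <- dt$binA > dt$binB
    tmp <- dt$binA[swap]; dt$binA[swap] <- dt$binB[swap]
    dt$binB[swap] <- tmp
    obs <- dt[, list(count = .N), by = c("binA", "binB")]
    obs$dist <- obs$binB - obs$binA
    obs <- obs[obs$dist >= minBins]
    if (!nrow(obs)) next
    obs$biasA <- bias[obs$binA + 1L]
    obs$biasB <- bias[obs$binB + 1L]
    obs <- obs[!is.na(obs$biasA) & !is.na(obs$biasB)]
    obs$norm <- obs$count / (obs$biasA * obs$biasB)
    nbins <- nrow(m)
    obs$chrom <- chrom
    obs$nPossible <- nbins - obs$dist   # possible bin pairs at distance
    tested[[chrom]] <- obs
  }
  tested <- data.table::rbindlist(tested)
  if (!nrow(tested))
    stop("no testable bin pairs beyond the minimum distance",
         call. = FALSE)

  ## distance strata: pooled expected normalized count per possible pair
  perD <- tested[, list(sumNorm = sum(norm), nOcc = .N), by = "dist"]
  data.table::setorder(perD, dist)
  nPoss <- tested[!duplicated(paste(tested$chrom, tested$dist)),
                  list(nPossible = sum(nPossible)),
                  by = "dist"]
  perD <- merge(perD, nPoss, by = "dist")
  data.table::setorder(perD, dist)

  ## merge sparse strata with neighbours
  stratum <- integer(nrow(perD))
  cur <- 1L; acc <- 0L
  for (i in seq_len(nrow(perD))) {
    stratum[i] <- cur
    acc <- acc + perD$nOcc[i]
    if (acc >= minStratumPairs && i < nrow(perD)) {
      cur <- cur + 1L; acc <- 0L
    }
  }
  ## if the last stratum stayed sparse, merge it into the previous one
  if (acc > 0L && acc < minStratumPairs && cur > 1L)
    stratum[stratum == cur] <- cur - 1L
  perD$stratum <- stratum
  strat <- perD[, list(
    expNorm = sum(sumNorm) / sum(nPossible),
    dMin = min(dist), dMax = max(dist), nOcc = sum(nOcc)),
    by = "stratum"]
  if (any(strat$nOcc < 1L))
    stop("insufficient data in a distance stratum after merging",
         call. = FALSE)
  ## smooth expectations across neighbouring strata (log-space mean)
  k <- nrow(strat)
  sm <- vapply(seq_len(k), function(i) {
    j <- max(1L, i - 1L):min(k, i + 1L)
    exp(mean(log(strat$expNorm[j])))
  }, numeric(1))
  strat$expNormSmooth <- sm

  lut <- numeric(max(perD$dist))
  for (i in seq_len(k))
    lut[seq.int(strat$dMin[i], strat$dMax[i])] <- strat$expNormSmooth[i]
  tested$expected <- lut[tested$dist] * tested$biasA * tested$biasB
  tested$pvalue <- ppois(tested$count - 1L, tested$expected,
                         lower.tail = FALSE)
  tested$pvalue <- pmin(pmax(tested$pvalue, .Machine$double.xmin), 1)

  calls <- data.frame(
    chromA = tested$chrom, binA = tested$binA,
    chromB = tested$chrom, binB = tested$binB,
    count = tested$count, expected = tested$expected,
    pvalue = tested$pvalue, stringsAsFactors = FALSE)
  methods::new("InteractionCalls", calls = calls,
               resolution = resolution, method = "stringent",
               sample = sample,
               settings = list(minDistance = minDistance,
                               minStratumPairs = minStratumPairs))
}

#' Permutation-based FDR cutoff on interaction p-values
#'
#' Finds the largest p-value cutoff such that, averaged over
#' \code{nPerm} random interaction sets of the same size drawn from the
#' tested universe, at most \code{alpha} of the random p-values fall at
#' or below the cutoff -- i.e. called interactions are unlikely to
#' appear in random sets.
#'
#' @param pvalues p-values of the candidate calls.
#' @param universe p-values of all tested interactions to draw random
#'   sets from (defaults to \code{pvalues}).
#' @param alpha nominal FDR level.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed; the cutoff is deterministic for a fixed
#'   seed.
#' @return list with \code{cutoff}, logical \code{significant} flags for
#'   \code{pvalues}, \code{alpha} and \code{nPerm}.
#' @export
permutationFdr <- function(pvalues, universe = pvalues, alpha = 0.05,
                           nPerm = 1000L, seed = 1L) {
  if (nPerm < 100L) stop("'nPerm' must be >= 100", call. = FALSE)
  if (!length(pvalues)) stop("no p-values supplied", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(pvalues)
  if (length(unique(universe)) == 1L) {
    warning("degenerate p-value distribution; cutoff set below minimum")
    cutoff <- min(universe) / 2
    return(list(cutoff = cutoff, significant = pvalues <= cutoff,
                alpha = alpha, nPerm = as.integer(nPerm)))
  }
  cand <- sort(unique(pvalues))
  ## the cutoff cannot exceed (roughly) the alpha-quantile of the
  ## universe, so only candidates below a generous bound need checking
  bound <- quantile(universe, min(1, 4 * alpha), names = FALSE)
  cand <- cand[cand <= bound]
  if (!length(cand)) cand <- min(pvalues)
  ## mean fraction of a random size-n draw at or below each candidate,
  ## estimated by Monte Carlo over nPerm draws from the universe
  meanFrac <- numeric(length(cand))
  for (b in seq_len(nPerm)) {
    draw <- sort(sample(universe, n, replace = TRUE))
    meanFrac <- meanFrac + findInterval(cand, draw) / n
  }
  meanFrac <- meanFrac / nPerm
  ok <- which(meanFrac <= alpha)
  cutoff <- if (length(ok)) cand[max(ok)] else 0
  list(cutoff = cutoff, significant = pvalues <= cutoff,
       alpha = alpha, nPerm = as.integer(nPerm))
}
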