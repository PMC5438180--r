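## Seeded simulation of Hi-C read pairs with planted structure.

# Inverse-CDF sampling of intra-chromosomal distances from a truncated
# shifted power law p(d) proportional to (d + d0)^(-alpha) on [1, L).
.sampleDecayDistance <- function(n, L, alpha, d0) {
  u <- runif(n)
  lo <- 1 + d0
  hi <- L + d0
  if (abs(alpha - 1) < 1e-9) {
    d <- lo * exp(u * log(hi / lo)) - d0
  } else {
    a1 <- 1 - alpha
    d <- (u * (hi^a1 - lo^a1) + lo^a1)^(1 / a1) - d0
  }
  pmax(1L, pmin(as.integer(floor(d)), as.integer(L) - 1L))
}

.randStrand <- function(n) sample(c("+", "-"), n, replace = TRUE)

#' Simulate Hi-C read pairs for one genotype and replicate
#'
#' Draws background intra-chromosomal pairs with power-law distance decay
#' \eqn{p(d) \propto (d + d_0)^{-\alpha}}, an inter-chromosomal uniform
#' background, and pairs routed through the planted loops of a
#' \linkS4class{SyntheticTruth}, weighted by each loop's intensity
#' multiplier for the requested genotype. Background pairs with an end in
#' a suppressed region are thinned by that region's genotype-specific
#' retention probability, so the realized number of pairs can fall
#' slightly below \code{nPairs}. The simulation is a pure function of its
#' arguments and \code{seed}; the replicate seed is
#' \code{seed + replicate}.
#'
#' @param genome a \linkS4class{HicGenome}.
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param genotype one of \code{genotypeNames(truth)}.
#' @param nPairs number of pairs to draw before suppression thinning.
#' @param decayAlpha decay exponent (> 0).
#' @param interFrac fraction of background pairs that are
#'   inter-chromosomal, in [0, 1).
#' @param loopFrac fraction of pairs routed through a planted loop when
#'   its multiplier is 1.
#' @param replicate replicate index (used for seed splitting and recorded
#'   in the output).
#' @param seed base integer seed.
#' @param d0 decay-law offset in bp (avoids the singularity at d = 0).
#' @param telomereBias,centromereBias fractions of inter-chromosomal
#'   pairs whose two ends are placed inside telomere or
#'   centromere/pericentromere masks, emulating the telomere and
#'   centromere clustering seen in real nuclei.
#' @param armBias fraction of intra-chromosomal background pairs confined
#'   to a single chromosome arm (compartment-like self-association).
#' @param duplicationRate optional fraction of emitted pairs duplicated
#'   verbatim (PCR-duplicate emulation; off by default).
#'
#' @return data.table with columns chromA, posA, strandA, chromB, posB,
#'   strandB, replicate; 0-based positions, canonically ordered ends.
#' @export
simulateReadPairs <- function(genome, truth, genotype, nPairs,
                              decayAlpha = 1.0, interFrac = 0.2,
                              loopFrac = 0.05, replicate = 1L, seed = 1L,
                              d0 = 1000, telomereBias = 0,
                              centromereBias = 0, armBias = 0,
                              duplicationRate = 0) {
  if (!genotype %in% truth@genotypes)
    stop("unknown genotype '", genotype, "'; expected one of: ",
         paste(truth@genotypes, collapse = ", "), call. = FALSE)
  .assertFraction(interFrac, "interFrac", open_upper = TRUE)
  if (decayAlpha <= 0) stop("'decayAlpha' must be > 0", call. = FALSE)
  .assertCount(nPairs, "nPairs")
  if (nPairs == 0) return(.emptyPairs())
  set.seed(.spawnSeed(seed, replicate))
  cs <- chromSizes(genome)
  chroms <- names(cs)

  ## how many pairs go through loops
  w <- truth@intensity[, genotype]
  nLoops <- length(w)
  pLoop <- if (nLoops) min(loopFrac * sum(w) / nLoops, 0.9) else 0
  nLoopPairs <- rbinom(1L, nPairs, pLoop)
  nBg <- nPairs - nLoopPairs

  parts <- list()

  ## planted-loop pairs
  if (nLoopPairs > 0) {
    li <- sample.int(nLoops, nLoopPairs, replace = TRUE, prob = w)
    uA <- truth@anchorA[li]; uB <- truth@anchorB[li]
    posA <- as.integer(floor(runif(nLoopPairs,
      GenomicRanges::start(uA) - 1L, GenomicRanges::end(uA))))
    posB <- as.integer(floor(runif(nLoopPairs,
      GenomicRanges::start(uB) - 1L, GenomicRanges::end(uB))))
    parts$loop <- data.table::data.table(
      chromA = as.character(GenomicRanges::seqnames(uA)), posA = posA,
      strandA = .randStrand(nLoopPairs),
      chromB = as.character(GenomicRanges::seqnames(uB)), posB = posB,
      strandB = .randStrand(nLoopPairs))
  }

  ## background: split inter/intra
  nInter <- rbinom(1L, nBg, interFrac)
  nIntra <- nBg - nInter

  if (nInter > 0 && length(chroms) >= 2L) {
    ## biased inter pairs cluster at a handful of focal points per mask
    ## interval (centromere/telomere contacts are punctate, not uniform)
    makeFoci <- function(mask, nFoci = 5L, width = 500L) {
      idx <- rep(seq_along(mask), each = nFoci)
      m <- mask[idx]
      s <- GenomicRanges::start(m) - 1L
      e <- pmax(GenomicRanges::end(m) - width, s + 1L)
      list(chrom = as.character(GenomicRanges::seqnames(m)),
           start = as.integer(floor(runif(length(idx), s, e))),
           width = width)
    }
    placeIn <- function(n, foci) {
      i <- sample.int(length(foci$chrom), n, replace = TRUE)
      list(chrom = foci$chrom[i],
           pos = foci$start[i] +
             as.integer(floor(runif(n, 0, foci$width))))
    }
    kind <- sample(c("tel", "cen", "bg"), nInter, replace = TRUE,
                   prob = c(telomereBias, centromereBias,
                            max(1 - telomereBias - centromereBias, 0)))
    drawInter <- function(n, mask = NULL) {
      if (n == 0) return(NULL)
      if (is.null(mask)) {
        cA <- sample(chroms, n, replace = TRUE, prob = cs)
        cB <- sample(chroms, n, replace = TRUE, prob = cs)
        same <- cA == cB
        while (any(same)) {   # resample until chromosomes differ
          cB[same] <- sample(chroms, sum(same), replace = TRUE, prob = cs)
          same <- cA == cB
        }
        pA <- as.integer(floor(runif(n, 0, cs[cA])))
        pB <- as.integer(floor(runif(n, 0, cs[cB])))
      } else {
        foci <- makeFoci(mask)
        a <- placeIn(n, foci); b <- placeIn(n, foci)
        same <- a$chrom == b$chrom
        while (any(same)) {   # redraw colliding B ends only
          rb <- placeIn(sum(same), foci)
          b$chrom[same] <- rb$chrom; b$pos[same] <- rb$pos
          same <- a$chrom == b$chrom
        }
        cA <- a$chrom; pA <- a$pos; cB <- b$chrom; pB <- b$pos
      }
      data.table::data.table(
        chromA = cA, posA = pA, strandA = .randStrand(n),
        chromB = cB, posB = pB, strandB = .randStrand(n))
    }
    parts$interTel <- drawInter(sum(kind == "tel"), telomeres(genome))
    parts$interCen <- drawInter(sum(kind == "cen"), centromeres(genome))
    parts$interBg <- drawInter(sum(kind == "bg"))
  } else if (nInter > 0) {
    nIntra <- nIntra + nInter   # single-chromosome genome: all intra
  }

  if (nIntra > 0) {
    chrom <- sample(chroms, nIntra, replace = TRUE, prob = cs)
    L <- cs[chrom]
    ## optionally confine a fraction to one arm (compartment structure)
    arm <- runif(nIntra) < armBias
    Leff <- L
    off <- integer(nIntra)
    if (any(arm)) {
      cen <- centromeres(genome)
      cenMid <- setNames(round((GenomicRanges::start(cen) +
                                  GenomicRanges::end(cen)) / 2),
                         as.character(GenomicRanges::seqnames(cen)))
      mid <- cenMid[chrom[arm]]
      pArm <- runif(sum(arm)) < mid / L[arm]      # pick arm by length
      Leff[arm] <- ifelse(pArm, mid, L[arm] - mid)
      off[arm] <- ifelse(pArm, 0L, as.integer(mid))
    }
    d <- .sampleDecayDistance(nIntra, Leff, decayAlpha, d0)
    posA <- off + as.integer(floor(runif(nIntra, 0, Leff - d)))
    posB <- posA + d
    parts$intra <- data.table::data.table(
      chromA = chrom, posA = posA, strandA = .randStrand(nIntra),
      chromB = chrom, posB = posB, strandB = .randStrand(nIntra))
  }

  bgNames <- setdiff(names(parts), "loop")
  bg <- data.table::rbindlist(parts[bgNames])

  ## genotype-specific suppression thinning of the background
  if (nrow(bg) && length(truth@suppression)) {
    keepP <- rep(1, nrow(bg))
    ret <- truth@retention[, genotype]
    grA <- .toGRanges(bg$chromA, bg$posA, bg$posA + 1L)
    grB <- .toGRanges(bg$chromB, bg$posB, bg$posB + 1L)
    for (gr in list(grA, grB)) {
      hits <- IRanges::findOverlaps(gr, truth@suppression)
      if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        keepP[q] <- keepP[q] * ret[S4Vectors::subjectHits(hits)]
      }
    }
    bg <- bg[runif(nrow(bg)) < keepP]
  }

  out <- data.table::rbindlist(c(list(bg),
                                 parts[intersect("loop", names(parts))]))
  if (duplicationRate > 0 && nrow(out)) {
    nd <- rbinom(1L, nrow(out), duplicationRate)
    if (nd > 0) out <- rbind(out, out[sample.int(nrow(out), nd)])
  }
  out <- .canonicalizePairs(out)
  out$replicate <- as.integer(replicate)
  data.table::setDT(out)
  data.table::setorder(out, chromA, posA, chromB, posB)
  out[]
}
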