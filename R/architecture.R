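## Genome-scale organization: compartment eigenvector, telomere
## metaplots, centromere inter-chromosomal fractions.

#' Compartment eigenvector of a chromosome contact matrix
#'
#' Computes the correlation matrix of per-bin contact profiles (1 Mb
#' bins by default in the pipeline), performs a principal component
#' analysis and returns the first component loading per bin -- the
#' compartment eigenvector separating broadly self-associating domains
#' such as chromosome arms. The sign convention makes the larger cluster
#' positive.
#'
#' @param m symmetric contact matrix for one chromosome.
#' @param minBins minimum usable (nonzero-mass) bins.
#' @return data.frame with bin (0-based index), loading and sign for
#'   usable bins.
#' @export
compartmentEigenvector <- function(m, minBins = 10L) {
  mass <- rowSums(m)
  usable <- mass > 0
  if (sum(usable) < minBins)
    stop("need at least ", minBins, " bins with contact mass",
         call. = FALSE)
  w <- m[usable, usable, drop = FALSE]
  v <- apply(w, 1L, sd)
  ok <- v > 0
  if (sum(ok) < minBins)
    stop("contact profiles are constant; eigenvector degenerate",
         call. = FALSE)
  w <- w[ok, ok, drop = FALSE]
  cc <- suppressWarnings(cor(w))
  cc[!is.finite(cc)] <- 0
  offdiag <- cc[upper.tri(cc)]
  if (max(abs(offdiag)) < 1e-10)
    stop("correlation matrix is the identity; eigenvector degenerate",
         call. = FALSE)
  ev <- eigen(cc, symmetric = TRUE)
  loading <- ev$vectors[, 1L]
  if (sum(loading >= 0) < sum(loading < 0)) loading <- -loading
  bins <- as.integer(rownames(m)[usable][ok])
  data.frame(bin = bins, loading = loading,
             sign = ifelse(loading >= 0, 1L, -1L))
}

.callEnds <- function(calls) {
  cl <- if (methods::is(calls, "InteractionCalls"))
    interactionCalls(calls) else calls
  res <- if (methods::is(calls, "InteractionCalls"))
    binResolution(calls) else attr(calls, "resolution")
  list(calls = cl, resolution = res)
}

#' Metaplot of inter-chromosomal interactions around telomeres
#'
#' Aligns every chromosome end (telomere) and averages, per offset bin,
#' the number of inter-chromosomal call ends falling at that distance
#' from the end. A telomere-clustered genome peaks at offset zero.
#'
#' @param calls an \linkS4class{InteractionCalls} (inter-chromosomal
#'   calls are extracted).
#' @param genome a \linkS4class{HicGenome}.
#' @param binSize offset bin width in bp.
#' @param flank how far from the chromosome end to profile, in bp.
#' @return data.frame with offset (bp from the chromosome end) and mean
#'   call-end count per telomere.
#' @export
telomereMetaplot <- function(calls, genome, binSize = 2e4, flank = 2e5) {
  cs <- chromSizes(genome)
  if (length(cs) < 2L)
    stop("inter-chromosomal metaplot needs at least two chromosomes",
         call. = FALSE)
  ce <- .callEnds(calls)
  cl <- ce$calls[ce$calls$chromA != ce$calls$chromB, , drop = FALSE]
  offsets <- seq(0, flank - binSize, by = binSize)
  if (nrow(cl) == 0L) {
    warning("no inter-chromosomal calls; empty profile")
    return(data.frame(offset = offsets,
                      mean_count = rep(0, length(offsets))))
  }
  res <- ce$resolution
  ends <- data.table::data.table(
    chrom = c(cl$chromA, cl$chromB),
    pos = c(cl$binA, cl$binB) * res + res / 2)
  ends$L <- cs[ends$chrom]
  dStart <- ends$pos
  dEnd <- ends$L - ends$pos
  d <- pmin(dStart, dEnd)
  sel <- d < flank
  counts <- tabulate(floor(d[sel] / binSize) + 1L,
                     nbins = length(offsets))
  nTel <- 2L * length(cs)
  data.frame(offset = offsets, mean_count = counts / nTel)
}

#' Fraction of inter-chromosomal calls joining centromeres
#'
#' Fraction of inter-chromosomal calls with both ends inside the
#' centromere/pericentromere mask, per replicate and pooled (the
#' centromere-clustering statistic; plotted as a percentage of total
#' inter-chromosomal calls).
#'
#' @param calls an \linkS4class{InteractionCalls}.
#' @param genome a \linkS4class{HicGenome}.
#' @param pericentromereFlank extra flank in bp added around the
#'   centromere mask.
#' @return data.frame with sample ("pooled" and each replicate) and
#'   fraction.
#' @export
centromereFractions <- function(calls, genome, pericentromereFlank = 0) {
  ce <- .callEnds(calls)
  cl <- ce$calls[ce$calls$chromA != ce$calls$chromB, , drop = FALSE]
  if (nrow(cl) == 0L)
    stop("no inter-chromosomal calls", call. = FALSE)
  res <- ce$resolution
  cen <- centromeres(genome)
  if (pericentromereFlank > 0)
    cen <- GenomicRanges::trim(suppressWarnings(
      GenomicRanges::resize(cen,
        GenomicRanges::width(cen) + 2 * pericentromereFlank,
        fix = "center")))
  cenBins <- .grToBins(cen, res)
  keyA <- paste(cl$chromA, cl$binA)
  keyB <- paste(cl$chromB, cl$binB)
  cenKey <- paste(cenBins$chrom, cenBins$bin)
  both <- keyA %in% cenKey & keyB %in% cenKey
  out <- data.frame(sample = "pooled", fraction = mean(both),
                    n_inter = nrow(cl), stringsAsFactors = FALSE)
  if ("replicate" %in% names(cl)) {
    for (r in sort(unique(cl$replicate))) {
      sel <- cl$replicate == r
      out <- rbind(out, data.frame(
        sample = paste0("rep", r), fraction = mean(both[sel]),
        n_inter = sum(sel), stringsAsFactors = FALSE))
    }
  }
  out
}
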