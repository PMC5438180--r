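## Bin classification (chromatin state, methylation, DMBs), mappability
## filtering, permutation-based overlap enrichment and replicate tests.

.binKey <- function(chrom, bin) paste(chrom, bin, sep = ":")

.trackTable <- function(track, resolution) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(track)),
    bin = .binIndex(GenomicRanges::start(track) - 1L, resolution),
    score = S4Vectors::mcols(track)$score)
}

#' Classify bins as active or inactive chromatin
#'
#' Splits the distribution of log2(H3K4me2 / H3K9me2) per bin at the
#' valley of a kernel density estimate between its two largest modes:
#' bins above the valley are active, below inactive. If the distribution
#' is unimodal the split falls back to a log-ratio of 0 with a warning.
#'
#' @param h3k4me2,h3k9me2 \code{GRanges} tracks with \code{score},
#'   binned on the same grid.
#' @param resolution bin width in bp.
#' @param pseudocount added to both signals before the ratio.
#' @return data.frame with chrom, bin, log_ratio and chromatin_state
#'   ("active"/"inactive"); the split point is attached as attribute
#'   \code{"valley"}.
#' @export
classifyChromatinState <- function(h3k4me2, h3k9me2, resolution = 250,
                                   pseudocount = 0.5) {
  if (length(h3k4me2) == 0L || length(h3k9me2) == 0L)
    stop("empty chromatin tracks", call. = FALSE)
  a <- .trackTable(h3k4me2, resolution)
  b <- .trackTable(h3k9me2, resolution)
  m <- merge(a, b, by = c("chrom", "bin"), suffixes = c(".a", ".b"))
  lr <- log2((m$score.a + pseudocount) / (m$score.b + pseudocount))
  valley <- .bimodalValley(lr)
  if (is.na(valley)) {
    warning("log-ratio distribution looks unimodal; ",
            "falling back to a split at 0")
    valley <- 0
  }
  out <- data.frame(chrom = m$chrom, bin = m$bin, log_ratio = lr,
                    chromatin_state = ifelse(lr > valley, "active",
                                             "inactive"),
                    stringsAsFactors = FALSE)
  attr(out, "valley") <- valley
  out
}

# valley of the KDE between the two highest modes; NA when unimodal
.bimodalValley <- function(x) {
  d <- density(x, n = 512)
  y <- d$y
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
               y[2:(n - 1)] > y[3:n], FALSE)
  peaks <- which(isMax & y > 0.05 * max(y))
  if (length(peaks) < 2L) return(NA_real_)
  top2 <- peaks[order(-y[peaks])][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- lo:hi
  d$x[between[which.min(y[between])]]
}

#' Label bins as high or low methylation
#'
#' A bin is "high" iff its methylation fraction is at or above the
#' context threshold (>= rule). Default thresholds per context are
#' implementation choices: 0.8 (CG), 0.4 (CHG), 0.1 (CHH).
#'
#' @param track \code{GRanges} methylation track with fractional
#'   \code{score}.
#' @param threshold high/low dividing value.
#' @param resolution bin width in bp.
#' @return data.frame with chrom, bin, level and meth_class.
#' @export
classifyMethylation <- function(track, threshold, resolution = 250) {
  tt <- .trackTable(track, resolution)
  if (nrow(tt) && (min(tt$score) < 0 || max(tt$score) > 1))
    stop("methylation fractions must lie in [0,1]", call. = FALSE)
  data.frame(chrom = tt$chrom, bin = tt$bin, level = tt$score,
             meth_class = ifelse(tt$score >= threshold, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Default methylation high/low thresholds per context
#' @return named numeric vector.
#' @export
methylationThresholds <- function() c(CG = 0.8, CHG = 0.4, CHH = 0.1)

#' Classify differentially methylated bins (DMBs)
#'
#' Among bins with high wild-type CHH methylation, bins whose
#' mutant/wild-type CHH ratio falls below 0.25 are differentially
#' methylated bins (RdDM targets, "nrpe1_DMB"); bins with ratio above
#' 0.75 are unchanged ("other_meCHH"); anything between (including the
#' boundaries exactly) is "neither". Bins with zero wild-type level are
#' excluded and counted.
#'
#' @param wtLevel,mutLevel numeric CHH fractions per bin (aligned).
#' @param high logical: bin is high-CHH in wild-type.
#' @param lowRatio,highRatio the two ratio boundaries.
#' @return character vector ("nrpe1_DMB", "other_meCHH", "neither", NA
#'   for non-high bins); excluded-bin count attached as attribute
#'   \code{"n_excluded"}.
#' @export
classifyDmbs <- function(wtLevel, mutLevel, high,
                         lowRatio = 0.25, highRatio = 0.75) {
  out <- rep(NA_character_, length(wtLevel))
  excl <- high & wtLevel == 0
  use <- high & !excl
  ratio <- mutLevel[use] / wtLevel[use]
  out[use] <- ifelse(ratio < lowRatio, "nrpe1_DMB",
                     ifelse(ratio > highRatio, "other_meCHH", "neither"))
  attr(out, "n_excluded") <- sum(excl)
  out
}

#' Filter features by Hi-C mappability
#'
#' Retains features overlapping at least one read in the
#' decrosslinked-control coverage track; removal counts are attached as
#' attribute \code{"n_removed"}.
#'
#' @param features \code{GRanges}.
#' @param control \code{GRanges} coverage track with \code{score}.
#' @return the mappable subset of \code{features}.
#' @export
mappabilityFilter <- function(features, control) {
  if (is.null(control)) stop("control track required", call. = FALSE)
  hits <- IRanges::findOverlaps(features, control)
  cov <- rep(0, length(features))
  if (length(hits)) {
    agg <- rowsum(S4Vectors::mcols(control)$score[
      S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
    cov[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out <- features[cov >= 1]
  attr(out, "n_removed") <- sum(cov < 1)
  out
}

#' Permutation-based overlap enrichment of calls at feature bins
#'
#' Observed statistic: the number of calls with at least one end in a
#' feature bin (a call with both ends in features counts once).
#' Expected: the mean of the same statistic over \code{nPerm} random
#' draws of equal-size bin sets from the universe of mappable
#' non-centromeric bins. The ratio is reported pooled and per
#' replicate; per-replicate ratios use the replicate's own observed and
#' expected counts, making them comparable across sequencing depths.
#'
#' @param calls an \linkS4class{InteractionCalls} or calls data.frame
#'   with attribute \code{"resolution"}.
#' @param featureBins data.frame with chrom and bin columns (e.g. from
#'   \code{.grToBins}) or a \code{GRanges}.
#' @param universe the bin universe to permute within (same formats).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with observed, expected (mean), expectedSd, ratio,
#'   perReplicate data.frame and nPerm.
#' @export
overlapEnrichment <- function(calls, featureBins, universe,
                              nPerm = 1000L, seed = 1L) {
  if (nPerm < 100L) stop("'nPerm' must be >= 100", call. = FALSE)
  ce <- .callEnds(calls)
  cl <- ce$calls
  res <- ce$resolution
  toBins <- function(x) {
    if (methods::is(x, "GRanges")) x <- .grToBins(x, res)
    unique(.binKey(x$chrom, x$bin))
  }
  featKeys <- toBins(featureBins)
  univKeys <- toBins(universe)
  featKeys <- intersect(featKeys, univKeys)
  if (!length(featKeys))
    stop("feature set empty after restriction to the universe",
         call. = FALSE)
  nFeat <- length(featKeys)
  nUniv <- length(univKeys)
  idA <- match(.binKey(cl$chromA, cl$binA), univKeys)
  idB <- match(.binKey(cl$chromB, cl$binB), univKeys)
  featIdx <- match(featKeys, univKeys)

  memb <- logical(nUniv)
  memb[featIdx] <- TRUE
  hit <- function(membership) {
    a <- !is.na(idA) & membership[pmax(idA, 1L)]
    b <- !is.na(idB) & membership[pmax(idB, 1L)]
    a | b
  }
  obsHit <- hit(memb)
  observed <- sum(obsHit)

  reps <- if ("replicate" %in% names(cl)) sort(unique(cl$replicate))
          else integer(0)
  set.seed(as.integer(seed))
  expTot <- numeric(nPerm)
  expRep <- matrix(0, nrow = nPerm, ncol = length(reps))
  for (b in seq_len(nPerm)) {
    pm <- logical(nUniv)
    pm[sample.int(nUniv, nFeat)] <- TRUE
    h <- hit(pm)
    expTot[b] <- sum(h)
    for (j in seq_along(reps))
      expRep[b, j] <- sum(h[cl$replicate == reps[j]])
  }
  expected <- mean(expTot)
  perRep <- NULL
  if (length(reps)) {
    perRep <- data.frame(
      replicate = reps,
      observed = vapply(reps, function(r)
        sum(obsHit[cl$replicate == r]), numeric(1)),
      expected = colMeans(expRep))
    perRep$ratio <- ifelse(perRep$expected > 0,
                           perRep$observed / perRep$expected, NA_real_)
  }
  list(observed = observed, expected = expected,
       expectedSd = sd(expTot),
       ratio = if (expected > 0) observed / expected else NA_real_,
       perReplicate = perRep, nPerm = as.integer(nPerm),
       nFeatureBins = nFeat, nUniverseBins = nUniv)
}

#' Methylation-matched comparison of DMB and other-meCHH enrichment
#'
#' Mode "low" keeps, in both categories, only bins with methylation
#' below the median DMB level; mode "high" keeps bins above the median
#' other-meCHH level. Enrichment is then computed per matched subset, so
#' differences between the categories cannot be explained by different
#' methylation levels.
#'
#' @param calls calls object passed to \code{\link{overlapEnrichment}}.
#' @param dmbBins,otherBins data.frames with chrom, bin and level
#'   columns.
#' @param universe bin universe.
#' @param mode "low" or "high".
#' @param nPerm,seed permutation parameters.
#' @return list with per-category enrichment results and the matching
#'   threshold.
#' @export
matchedComparison <- function(calls, dmbBins, otherBins, universe,
                              mode = c("low", "high"), nPerm = 1000L,
                              seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "low") {
    thr <- median(dmbBins$level)
    dmb <- dmbBins[dmbBins$level < thr, , drop = FALSE]
    oth <- otherBins[otherBins$level < thr, , drop = FALSE]
  } else {
    thr <- median(otherBins$level)
    dmb <- dmbBins[dmbBins$level > thr, , drop = FALSE]
    oth <- otherBins[otherBins$level > thr, , drop = FALSE]
  }
  if (!nrow(dmb))
    stop("DMB subset empty after '", mode, "' matching", call. = FALSE)
  if (!nrow(oth))
    stop("other-meCHH subset empty after '", mode, "' matching",
         call. = FALSE)
  list(mode = mode, threshold = thr,
       dmb = overlapEnrichment(calls, dmb, universe, nPerm, seed),
       other = overlapEnrichment(calls, oth, universe, nPerm, seed),
       nDmb = nrow(dmb), nOther = nrow(oth))
}

#' Two-sided paired t-test across biological replicates
#'
#' Standard paired t statistic on per-replicate values. Degenerate
#' inputs are handled explicitly: identical vectors give p = 1;
#' zero-variance nonzero differences are flagged and reported as p = 0.
#'
#' @param a,b per-replicate values (equal length >= 2).
#' @return list with statistic, p.value and a \code{degenerate} flag.
#' @export
replicateTtest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need >= 2 paired replicate values", call. = FALSE)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, p.value = 1, degenerate = TRUE))
    return(list(statistic = sign(mean(d)) * Inf, p.value = 0,
                degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       degenerate = FALSE)
}

# bins (chrom:bin keys) of call ends at the call resolution
.callEndKeys <- function(cl) {
  list(a = .binKey(cl$chromA, cl$binA), b = .binKey(cl$chromB, cl$binB))
}

#' DMRs with detectable interactions, per genotype and score cutoff
#'
#' Counts, for each genotype and each score cutoff, the DMRs anchored by
#' at least one scored call (a DMR counts once however many calls touch
#' it) and reports the count as a ratio to the wild-type count, pooled
#' and per replicate.
#'
#' @param callsByGenotype named list of scored
#'   \linkS4class{InteractionCalls}, one per genotype.
#' @param dmrs \code{GRanges} of (mappability-filtered) DMRs.
#' @param cutoffs score cutoffs to evaluate.
#' @param wildType name of the wild-type entry in
#'   \code{callsByGenotype}.
#' @return data.frame with genotype, cutoff, replicate ("pooled" or the
#'   replicate id), n_dmrs_with_call and ratio_to_wt.
#' @export
dmrLoopCounts <- function(callsByGenotype, dmrs,
                          cutoffs = c(5, 10, 15), wildType = "Col0") {
  if (!wildType %in% names(callsByGenotype))
    stop("wild-type sample '", wildType, "' not in callsByGenotype",
         call. = FALSE)
  res <- binResolution(callsByGenotype[[1L]])
  ## each DMR's set of covered bin keys, computed once
  dmrKeyList <- lapply(seq_along(dmrs), function(i) {
    b <- .grToBins(dmrs[i], res)
    unique(.binKey(b$chrom, b$bin))
  })
  hitsPerDmr <- function(cl) {
    keys <- .callEndKeys(cl)
    allKeys <- unique(c(keys$a, keys$b))
    vapply(dmrKeyList, function(k) any(k %in% allKeys), logical(1))
  }
  rows <- list()
  perG <- list()
  for (g in names(callsByGenotype)) {
    sc <- interactionCalls(callsByGenotype[[g]])
    if (!"score" %in% names(sc))
      stop("calls for '", g, "' are not scored", call. = FALSE)
    for (cut in cutoffs) {
      cl <- sc[sc$score >= cut, , drop = FALSE]
      labs <- c("pooled", if ("replicate" %in% names(cl))
        as.character(sort(unique(sc$replicate))))
      for (lab in labs) {
        sub <- if (lab == "pooled") cl else
          cl[cl$replicate == as.integer(sub("rep", "", lab)), ,
             drop = FALSE]
        n <- sum(hitsPerDmr(sub))
        perG[[paste(g, cut, lab)]] <- n
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = g, cutoff = cut, replicate = lab,
          n_dmrs_with_call = n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$ratio_to_wt <- NA_real_
  for (i in seq_len(nrow(out))) {
    wtN <- perG[[paste(wildType, out$cutoff[i], out$replicate[i])]]
    if (!is.null(wtN) && wtN > 0)
      out$ratio_to_wt[i] <- out$n_dmrs_with_call[i] / wtN
  }
  out
}

#' DMR loop counts stratified by nucleosome change
#'
#' Splits DMRs into those overlapping a nucleosome reduced in the mutant
#' (any overlapping MNase-ratio bin strictly above \code{threshold})
#' and those not, then computes \code{\link{dmrLoopCounts}} per stratum.
#'
#' @param callsByGenotype named list of scored calls.
#' @param dmrs \code{GRanges} of DMRs.
#' @param mnaseRatio \code{GRanges} track of wild-type/mutant MNase
#'   ratios.
#' @param threshold ratio above which a nucleosome counts as reduced
#'   (strict >).
#' @param cutoffs,wildType as in \code{\link{dmrLoopCounts}}.
#' @return data.frame with a stratum column ("reduced"/"not_reduced").
#' @export
nucleosomeStratifiedCounts <- function(callsByGenotype, dmrs, mnaseRatio,
                                       threshold = 2,
                                       cutoffs = c(5, 10, 15),
                                       wildType = "Col0") {
  hits <- IRanges::findOverlaps(dmrs, mnaseRatio)
  reduced <- rep(FALSE, length(dmrs))
  if (length(hits)) {
    ## strict >: a ratio exactly at the threshold is "not reduced"
    above <- tapply(
      S4Vectors::mcols(mnaseRatio)$score[S4Vectors::subjectHits(hits)] >
        threshold, S4Vectors::queryHits(hits), any)
    reduced[as.integer(names(above))] <- as.logical(above)
  }
  out <- list()
  for (stratum in c("reduced", "not_reduced")) {
    sel <- if (stratum == "reduced") reduced else !reduced
    if (!any(sel)) next
    tab <- dmrLoopCounts(callsByGenotype, dmrs[sel], cutoffs, wildType)
    tab$stratum <- stratum
    out[[stratum]] <- tab
  }
  do.call(rbind, out)
}
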