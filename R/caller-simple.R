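## The simple (loose) interaction caller: count threshold derived from
## the shortest allowed bin distance, applied genome-wide, plus the
## interaction score.

#' Derive the read-count threshold from short-range bin pairs
#'
#' Takes all intra-chromosomal bin pairs at the derivation distance
#' (default 4 bins, the shortest distance the caller admits) and finds
#' the smallest integer count \code{t} such that the fraction of those
#' bin pairs with count >= \code{t} is at most \code{topFraction}
#' (default the top 5\%). The threshold is floored at 2 reads: every call
#' must be supported by at least two independent ligation events. Ties at
#' the boundary resolve to never exceeding the nominal fraction.
#'
#' @param binned a \linkS4class{BinnedContacts} (e.g. at 250 bp).
#' @param distance derivation distance in bins.
#' @param topFraction fraction of derivation-distance pairs to keep.
#' @return list with elements \code{threshold}, \code{distance},
#'   \code{topFraction} and \code{nDerivationPairs}.
#' @export
deriveCountThreshold <- function(binned, distance = 4L,
                                 topFraction = 0.05) {
  cts <- contactCounts(binned)
  sel <- cts$chromA == cts$chromB & (cts$binB - cts$binA) == distance
  counts <- cts$count[sel]
  if (!length(counts))
    stop("no bin pairs at derivation distance ", distance,
         "; deeper input needed", call. = FALSE)
  t <- .smallestTailThreshold(counts, topFraction)
  list(threshold = max(t, 2L), distance = as.integer(distance),
       topFraction = topFraction, nDerivationPairs = length(counts))
}

# smallest integer t with mean(counts >= t) <= fraction
.smallestTailThreshold <- function(counts, fraction) {
  for (t in seq.int(min(counts), max(counts) + 1L)) {
    if (mean(counts >= t) <= fraction) return(as.integer(t))
  }
  as.integer(max(counts) + 1L)
}

#' Call interactions with the simple distance/count filter
#'
#' Keeps intra-chromosomal bin pairs at least \code{minDistance} bins
#' apart whose read count reaches \code{max(threshold, minReads)}, and
#' inter-chromosomal bin pairs under the same count rule (the distance
#' rule is undefined across chromosomes). With
#' \code{includeDerivationDistance = FALSE} the derivation-distance pairs
#' only set the threshold and are excluded from the call set.
#'
#' @param binned a \linkS4class{BinnedContacts}.
#' @param threshold result of \code{\link{deriveCountThreshold}} (or an
#'   integer count).
#' @param minDistance minimum intra-chromosomal separation in bins.
#' @param minReads absolute floor on supporting reads.
#' @param sample sample label recorded on the calls.
#' @param includeDerivationDistance keep bin pairs at exactly the
#'   derivation distance as calls.
#' @return an \linkS4class{InteractionCalls} with method "simple".
#' @export
callSimple <- function(binned, threshold, minDistance = 4L,
                       minReads = 2L, sample = "sample",
                       includeDerivationDistance = TRUE) {
  thr <- if (is.list(threshold)) threshold$threshold else threshold
  minCount <- max(thr, minReads)
  cts <- data.table::as.data.table(contactCounts(binned))
  intra <- cts$chromA == cts$chromB
  dist <- ifelse(intra, cts$binB - cts$binA, NA_integer_)
  minD <- if (includeDerivationDistance) minDistance else minDistance + 1L
  keep <- cts$count >= minCount & (!intra | dist >= minD)
  calls <- as.data.frame(cts[keep])
  methods::new("InteractionCalls", calls = calls,
               resolution = binResolution(binned), method = "simple",
               sample = sample,
               settings = list(threshold = as.integer(minCount),
                               minDistance = as.integer(minD),
                               minReads = as.integer(minReads)))
}

#' Attach interaction scores to simple calls
#'
#' The interaction score of a call is its supporting read count
#' multiplied by the ratio of the sample's total retained read pairs to
#' the total number of loops called in that sample:
#' \code{score = count * totalReads / nLoops}. Scores are monotone in
#' count within a sample, so score cutoffs give nested call sets.
#'
#' @param calls an \linkS4class{InteractionCalls}.
#' @param totalReads total retained read pairs in the sample (after site
#'   filtering).
#' @return the calls with a \code{score} column.
#' @export
scoreCalls <- function(calls, totalReads) {
  cl <- interactionCalls(calls)
  if (nrow(cl) == 0L)
    stop("cannot score an empty call set", call. = FALSE)
  cl$score <- cl$count * (totalReads / nrow(cl))
  methods::initialize(calls, calls = cl,
                      settings = c(callerSettings(calls),
                                   list(totalReads = totalReads)))
}

#' Filter scored calls at a score cutoff
#' @param calls a scored \linkS4class{InteractionCalls}.
#' @param cutoff minimum score (>= rule).
#' @return the calls restricted to \code{score >= cutoff}.
#' @export
filterByScore <- function(calls, cutoff) {
  cl <- interactionCalls(calls)
  if (!"score" %in% names(cl))
    stop("calls are not scored; run scoreCalls() first", call. = FALSE)
  methods::initialize(calls, calls = cl[cl$score >= cutoff, , drop = FALSE],
                      settings = c(callerSettings(calls),
                                   list(scoreCutoff = cutoff)))
}
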