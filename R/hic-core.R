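## Hi-C core: pair ingestion, restriction-site filtering, binning, decay
## curves, contact matrices and replicate correlation.

#' Load a read-pair table from disk
#'
#' Reads the 7-column tab-separated pairs format (chromA posA strandA
#' chromB posB strandB replicate), validates rows and applies canonical
#' end ordering. Malformed rows (negative or non-numeric positions,
#' positions beyond chromosome bounds) are dropped and counted; more than
#' 1\% malformed rows is a hard error, as is any unknown chromosome.
#'
#' @param path pairs file path.
#' @param genome optional \linkS4class{HicGenome} for bounds/chromosome
#'   validation.
#' @return data.table of canonical pairs; the number of rejected rows is
#'   attached as attribute \code{"n_malformed"}.
#' @export
loadPairs <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, sep = "\t", header = TRUE,
                        colClasses = list(character = c(1, 3, 4, 6)))),
    error = function(e) stop("cannot parse pairs file: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L) {
    warning("empty pairs file: ", path, call. = FALSE)
    out <- .emptyPairs()
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  data.table::setnames(dt, .pairColumns[seq_len(ncol(dt))])
  posA <- suppressWarnings(as.numeric(dt$posA))
  posB <- suppressWarnings(as.numeric(dt$posB))
  bad <- is.na(posA) | is.na(posB) | posA < 0 | posB < 0
  if (!is.null(genome)) {
    cs <- chromSizes(genome)
    unknown <- setdiff(unique(c(dt$chromA, dt$chromB)), names(cs))
    if (length(unknown))
      stop("unknown chromosome(s) in pairs file: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- bad | posA >= cs[dt$chromA] | posB >= cs[dt$chromB]
  }
  nBad <- sum(bad)
  if (nBad / nrow(dt) > 0.01)
    stop(sprintf("%d of %d rows malformed (> 1%%)", nBad, nrow(dt)),
         call. = FALSE)
  dt <- dt[!bad]
  dt$posA <- as.integer(posA[!bad])
  dt$posB <- as.integer(posB[!bad])
  if (!"replicate" %in% names(dt)) dt$replicate <- 1L
  dt <- .canonicalizePairs(dt)
  attr(dt, "n_malformed") <- nBad
  dt
}

#' Count restriction sites strictly between two positions
#'
#' Number of cut sites strictly inside the open interval
#' (min(a, b), max(a, b)) on one chromosome; symmetric in its arguments.
#' Vectorized over \code{a}/\code{b}.
#'
#' @param genome a \linkS4class{HicGenome} (or a named list of sorted
#'   site vectors).
#' @param chrom chromosome name.
#' @param a,b positions in bp (0-based).
#' @return integer vector of site counts.
#' @examples
#' gn <- generateGenome(1, 1e5, seed = 1)
#' sitesBetween(gn, "chr1", 0, 50000)
#' @export
sitesBetween <- function(genome, chrom, a, b) {
  sites <- if (methods::is(genome, "HicGenome"))
    restrictionSites(genome) else genome
  if (!chrom %in% names(sites))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  s <- sites[[chrom]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  # sites x with lo < x < hi: findInterval on half-open grid
  ge_hi <- findInterval(hi - 1L, s)        # sites <= hi - 1, i.e. < hi
  le_lo <- findInterval(lo, s)             # sites <= lo
  as.integer(pmax(ge_hi - le_lo, 0L))
}

#' Filter read pairs by restriction-site separation
#'
#' Keeps intra-chromosomal pairs only when strictly more than
#' \code{minSites} cut sites lie between their two ends (removing
#' self-ligation and adjacent-fragment artefacts); inter-chromosomal
#' pairs are exempt since the rule is distance-based. Filter statistics
#' are attached as attribute \code{"filter_stats"}.
#'
#' @param pairs pairs table.
#' @param genome a \linkS4class{HicGenome}.
#' @param minSites minimum strictly-exceeded site count (default 3).
#' @return filtered pairs table.
#' @export
filterPairsBySites <- function(pairs, genome, minSites = 3L) {
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0L) return(pairs)
  cs <- chromSizes(genome)
  miss <- setdiff(unique(c(pairs$chromA, pairs$chromB)), names(cs))
  if (length(miss))
    stop("restriction map does not cover: ",
         paste(miss, collapse = ", "), call. = FALSE)
  intra <- .isIntra(pairs)
  keep <- rep(TRUE, nrow(pairs))
  for (chrom in unique(pairs$chromA[intra])) {
    sel <- which(intra & pairs$chromA == chrom)
    n <- sitesBetween(genome, chrom, pairs$posA[sel], pairs$posB[sel])
    keep[sel] <- n > minSites
  }
  out <- pairs[keep]
  attr(out, "filter_stats") <- list(
    input = nrow(pairs), kept = nrow(out),
    removed_intra = sum(!keep), inter = sum(!intra))
  out
}

#' Bin read pairs into fixed-width genomic bins
#'
#' Assigns each end to \code{floor(pos / resolution)} (half-open bins on
#' 0-based positions) and aggregates pair counts per bin pair. Counts sum
#' to the number of input pairs.
#'
#' @param pairs pairs table.
#' @param resolution bin width in bp (> 0).
#' @param byReplicate aggregate per replicate instead of pooled.
#' @return a \linkS4class{BinnedContacts}.
#' @export
binPairs <- function(pairs, resolution = 250, byReplicate = FALSE) {
  if (resolution <= 0) stop("'resolution' must be > 0", call. = FALSE)
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0L) {
    cts <- data.table::data.table(
      chromA = character(), binA = integer(), chromB = character(),
      binB = integer(), count = integer())
    if (byReplicate) cts$replicate <- integer()
    return(methods::new("BinnedContacts", counts = as.data.frame(cts),
                        resolution = resolution, nPairs = 0))
  }
  dt <- data.table::data.table(
    chromA = pairs$chromA, binA = .binIndex(pairs$posA, resolution),
    chromB = pairs$chromB, binB = .binIndex(pairs$posB, resolution),
    replicate = if ("replicate" %in% names(pairs))
      pairs$replicate else 1L)
  dt <- .canonicalizeBins(dt)
  keys <- c("chromA", "binA", "chromB", "binB",
            if (byReplicate) "replicate")
  cts <- dt[, list(count = .N), by = keys]
  data.table::setorderv(cts, keys)
  methods::new("BinnedContacts", counts = as.data.frame(cts),
               resolution = resolution, nPairs = nrow(pairs))
}

#' Distance decay curve of intra-chromosomal contacts
#'
#' Optionally assigns each read end to its containing restriction
#' fragment first (using the fragment midpoint, the fragment-assignment
#' convention for decay plots), then bins pair distances at
#' \code{resolution} bp and tabulates counts per distance bin. Counts sum
#' to the number of retained intra-chromosomal pairs.
#'
#' @param pairs pairs table (already site-filtered, or supply
#'   \code{genome} and \code{minSites} to filter here).
#' @param genome optional \linkS4class{HicGenome}; needed for
#'   fragment assignment and/or filtering.
#' @param resolution distance bin width in bp.
#' @param fragmentAssign assign ends to restriction-fragment midpoints
#'   before binning.
#' @param minSites if non-NULL, apply \code{\link{filterPairsBySites}}.
#' @return data.frame with distance (bin midpoint lower bound, bp) and
#'   count.
#' @export
decayCurve <- function(pairs, genome = NULL, resolution = 250,
                       fragmentAssign = FALSE, minSites = NULL) {
  pairs <- data.table::as.data.table(pairs)
  if (!is.null(minSites)) {
    if (is.null(genome))
      stop("'genome' required for site filtering", call. = FALSE)
    pairs <- filterPairsBySites(pairs, genome, minSites)
  }
  intra <- pairs[.isIntra(pairs)]
  if (nrow(intra) == 0L)
    return(data.frame(distance = numeric(), count = integer()))
  posA <- intra$posA; posB <- intra$posB
  if (fragmentAssign) {
    if (is.null(genome))
      stop("'genome' required for fragment assignment", call. = FALSE)
    mids <- .fragmentMidpoints(genome)
    for (chrom in unique(intra$chromA)) {
      sel <- intra$chromA == chrom
      m <- mids[[chrom]]
      posA[sel] <- m[.fragmentIndex(genome, chrom, posA[sel])]
      posB[sel] <- m[.fragmentIndex(genome, chrom, posB[sel])]
    }
  }
  d <- abs(posB - posA)
  db <- .binIndex(d, resolution) * resolution
  tab <- data.table::data.table(distance = db)[, list(count = .N),
                                               by = "distance"]
  data.table::setorder(tab, distance)
  as.data.frame(tab)
}

# fragment index of a position: fragment k spans [site_k, site_{k+1})
# with sentinel boundaries at 0 and chromosome end.
.fragmentBreaks <- function(genome, chrom) {
  c(0L, restrictionSites(genome)[[chrom]],
    chromSizes(genome)[[chrom]])
}
.fragmentIndex <- function(genome, chrom, pos) {
  findInterval(pos, .fragmentBreaks(genome, chrom))
}
.fragmentMidpoints <- function(genome) {
  lapply(names(chromSizes(genome)), function(chrom) {
    br <- .fragmentBreaks(genome, chrom)
    as.integer(floor((head(br, -1) + tail(br, -1)) / 2))
  }) |> setNames(names(chromSizes(genome)))
}

#' Fit the decay exponent from a decay curve
#'
#' Log-log regression of contact counts on shifted distance
#' \code{(d + d0)} over a fitting range well above the decay offset and
#' below the truncation scale.
#'
#' @param curve data.frame from \code{\link{decayCurve}}.
#' @param d0 decay offset used by the generator (bp).
#' @param range fitting range in bp (default 20 * d0 to the 95th
#'   percentile of observed distances / 4).
#' @return fitted slope (negative of the decay exponent).
#' @export
fitDecaySlope <- function(curve, d0 = 1000, range = NULL) {
  if (is.null(range)) {
    dmax <- max(curve$distance)
    range <- c(20 * d0, dmax / 4)
  }
  sel <- curve$distance >= range[1] & curve$distance <= range[2] &
    curve$count > 0
  if (sum(sel) < 5) stop("too few distance bins in fitting range",
                         call. = FALSE)
  fit <- stats::lm(log(count) ~ log(distance + d0), data = curve[sel, ])
  unname(stats::coef(fit)[2])
}

#' Per-chromosome(-pair) contact matrix
#'
#' Dense symmetric contact matrix at \code{resolution} for one
#' chromosome (intra) from raw pairs or an existing binning whose
#' resolution divides the target. Total matrix mass equals twice the
#' pair count off-diagonal plus the diagonal (the matrix is
#' symmetrized), so row sums are per-bin marginals.
#'
#' @param x pairs table or \linkS4class{BinnedContacts}.
#' @param chrom chromosome to extract.
#' @param resolution target bin width in bp.
#' @param genome a \linkS4class{HicGenome} (for the bin count).
#' @return numeric matrix (bins x bins) with dimnames of bin indices.
#' @export
contactMatrix <- function(x, chrom, resolution, genome) {
  nbins <- as.integer(ceiling(chromSizes(genome)[[chrom]] / resolution))
  if (methods::is(x, "BinnedContacts")) {
    if (resolution %% binResolution(x) != 0)
      stop("source resolution ", binResolution(x),
           " does not divide target ", resolution, call. = FALSE)
    f <- resolution / binResolution(x)
    cts <- data.table::as.data.table(contactCounts(x))
    cts <- cts[cts$chromA == chrom & cts$chromB == chrom]
    dt <- data.table::data.table(
      binA = as.integer(cts$binA %/% f),
      binB = as.integer(cts$binB %/% f), count = cts$count)
  } else {
    p <- data.table::as.data.table(x)
    p <- p[p$chromA == chrom & p$chromB == chrom]
    dt <- data.table::data.table(
      binA = .binIndex(p$posA, resolution),
      binB = .binIndex(p$posB, resolution), count = 1L)
  }
  m <- matrix(0, nbins, nbins)
  if (nrow(dt)) {
    agg <- dt[, list(count = sum(count)), by = c("binA", "binB")]
    idx <- cbind(agg$binA + 1L, agg$binB + 1L)
    m[idx] <- m[idx] + agg$count
    m <- m + t(m) - diag(diag(m))
  }
  dimnames(m) <- list(seq_len(nbins) - 1L, seq_len(nbins) - 1L)
  m
}

#' Pearson correlation of contact counts between two samples
#'
#' Bins both samples at the same resolution, normalizes each bin-pair
#' count by the sample's total contact count (sequencing-depth
#' normalization), joins on the union of bin pairs (absent = 0) and
#' returns the Pearson correlation.
#'
#' @param countsA,countsB \linkS4class{BinnedContacts} at the same
#'   resolution.
#' @return Pearson r.
#' @export
replicateCorrelation <- function(countsA, countsB) {
  if (binResolution(countsA) != binResolution(countsB))
    stop("samples must be binned at the same resolution", call. = FALSE)
  a <- data.table::as.data.table(contactCounts(countsA))
  b <- data.table::as.data.table(contactCounts(countsB))
  a <- a[, list(count = sum(count)),
         by = c("chromA", "binA", "chromB", "binB")]
  b <- b[, list(count = sum(count)),
         by = c("chromA", "binA", "chromB", "binB")]
  a$va <- a$count / sum(a$count)
  b$vb <- b$count / sum(b$count)
  m <- merge(a[, -"count"], b[, -"count"],
             by = c("chromA", "binA", "chromB", "binB"), all = TRUE)
  m$va[is.na(m$va)] <- 0
  m$vb[is.na(m$vb)] <- 0
  if (sd(m$va) == 0 || sd(m$vb) == 0)
    stop("zero-variance contact counts: correlation undefined",
         call. = FALSE)
  cor(m$va, m$vb)
}

#' Pool read pairs across replicates
#'
#' Concatenates pair tables (replicate ids are preserved in the
#' \code{replicate} column); all inputs must come from the same genome.
#'
#' @param pairsList list of pairs tables.
#' @param genome optional \linkS4class{HicGenome}; when given, all
#'   chromosomes are checked against it.
#' @return pooled pairs table.
#' @export
combineReplicates <- function(pairsList, genome = NULL) {
  if (!length(pairsList)) return(.emptyPairs())
  out <- data.table::rbindlist(lapply(pairsList,
                                      data.table::as.data.table))
  if (!is.null(genome)) {
    miss <- setdiff(unique(c(out$chromA, out$chromB)),
                    names(chromSizes(genome)))
    if (length(miss))
      stop("genome mismatch; unknown chromosome(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  out
}
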