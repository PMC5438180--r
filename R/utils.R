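## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats cor density median pnorm ppois quantile rbinom
#'   rlnorm rnorm rpois runif sd t.test wilcox.test setNames
#' @importFrom utils head read.table write.table tail
#' @import data.table
NULL

# Replicate seeds derive from the base seed by simple addition so the
# splitting rule is reproducible and documentable.
.spawnSeed <- function(base_seed, k) {
  as.integer(base_seed) + as.integer(k)
}

.assertCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("'%s' must be a single finite number >= %s", name, min),
         call. = FALSE)
  invisible(x)
}

.assertFraction <- function(x, name, open_upper = FALSE) {
  bad <- length(x) != 1L || !is.finite(x) || x < 0 ||
    (if (open_upper) x >= 1 else x > 1)
  if (bad)
    stop(sprintf("'%s' must be a fraction in [0,%s", name,
                 if (open_upper) "1)" else "1]"), call. = FALSE)
  invisible(x)
}

# 0-based position -> 0-based bin index at `resolution` bp.
.binIndex <- function(pos, resolution) {
  as.integer(pos %/% resolution)
}

# GRanges (1-based closed) -> data.table of unique 0-based bins it covers.
.grToBins <- function(gr, resolution) {
  if (length(gr) == 0L)
    return(data.table::data.table(chrom = character(), bin = integer()))
  s <- GenomicRanges::start(gr) - 1L          # 0-based inclusive
  e <- GenomicRanges::end(gr) - 1L            # 0-based last covered base
  b0 <- .binIndex(s, resolution)
  b1 <- .binIndex(e, resolution)
  n <- b1 - b0 + 1L
  dt <- data.table::data.table(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), n),
    bin   = unlist(lapply(seq_along(gr), function(i) b0[i]:b1[i])))
  unique(dt)
}

# 0-based half-open interval columns -> GRanges (1-based closed).
.toGRanges <- function(chrom, start0, end0, strand = "*", seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand)
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <-
      seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

# Canonical end ordering: (chromA, posA) <= (chromB, posB).
.canonicalizePairs <- function(dt) {
  swap <- dt$chromA > dt$chromB |
    (dt$chromA == dt$chromB & dt$posA > dt$posB)
  if (any(swap)) {
    tmpc <- dt$chromA[swap]; tmpp <- dt$posA[swap]; tmps <- dt$strandA[swap]
    dt$chromA[swap] <- dt$chromB[swap]
    dt$posA[swap] <- dt$posB[swap]
    dt$strandA[swap] <- dt$strandB[swap]
    dt$chromB[swap] <- tmpc
    dt$posB[swap] <- tmpp
    dt$strandB[swap] <- tmps
  }
  dt
}

.pairColumns <- c("chromA", "posA", "strandA",
                  "chromB", "posB", "strandB", "replicate")

.emptyPairs <- function() {
  data.table::data.table(
    chromA = character(), posA = integer(), strandA = character(),
    chromB = character(), posB = integer(), strandB = character(),
    replicate = integer())
}

# Canonical bin-pair ordering used throughout.
.canonicalizeBins <- function(dt) {
  swap <- dt$chromA > dt$chromB |
    (dt$chromA == dt$chromB & dt$binA > dt$binB)
  if (any(swap)) {
    tmpc <- dt$chromA[swap]; tmpb <- dt$binA[swap]
    dt$chromA[swap] <- dt$chromB[swap]
    dt$binA[swap] <- dt$binB[swap]
    dt$chromB[swap] <- tmpc
    dt$binB[swap] <- tmpb
  }
  dt
}

.isIntra <- function(dt) dt$chromA == dt$chromB

# GRanges concatenation without Seqinfo-merge chatter (the generators
# build ranges chromosome by chromosome).
.cGR <- function(...) suppressWarnings(c(...))
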