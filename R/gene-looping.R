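## Gene-centred interaction statistics: promoters, expression groups,
## TF connections, TSS x DMR surfaces, gene-DMR connections, AGO4
## localization classes.

#' Strand-aware putative promoters (1 kb upstream of the TSS)
#'
#' Plus-strand gene with TSS t gets the 0-based half-open interval
#' [t - upstream, t); minus-strand [t, t + upstream). Intervals are
#' clipped at chromosome edges.
#'
#' @param genes gene table (gene_id, chrom, strand, tss).
#' @param genome a \linkS4class{HicGenome} for chromosome bounds.
#' @param upstream promoter length in bp.
#' @return \code{GRanges} with gene_id metadata.
#' @export
definePromoters <- function(genes, genome, upstream = 1000L) {
  cs <- chromSizes(genome)
  if (any(genes$tss < 0 | genes$tss >= cs[genes$chrom]))
    stop("TSS outside chromosome bounds", call. = FALSE)
  plus <- genes$strand == "+"
  s0 <- ifelse(plus, pmax(genes$tss - upstream, 0L), genes$tss)
  e0 <- ifelse(plus, genes$tss,
               pmin(genes$tss + upstream, cs[genes$chrom]))
  keep <- e0 > s0
  gr <- .toGRanges(genes$chrom[keep], as.integer(s0[keep]),
                   as.integer(e0[keep]), strand = genes$strand[keep])
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id[keep]
  gr
}

#' Inactive / middle / active gene groups by expression
#'
#' Ranks genes by RPKM (ties broken by gene id for determinism) and
#' returns the lowest \code{fraction} (inactive), the \code{fraction}
#' centred at the median rank (middle), and the highest \code{fraction}
#' (active).
#'
#' @param genes gene table restricted to mappable promoters.
#' @param genotype which rpkm_<genotype> column to rank by.
#' @param fraction group size as a fraction of genes.
#' @return list of gene-id vectors (inactive, middle, active) plus the
#'   group size n.
#' @export
expressionGroups <- function(genes, genotype, fraction = 0.05) {
  rpkm <- genes[[paste0("rpkm_", genotype)]]
  if (is.null(rpkm)) stop("no rpkm column for ", genotype, call. = FALSE)
  N <- nrow(genes)
  n <- round(fraction * N)
  if (n < 1L)
    stop("fewer genes than 1/fraction; cannot form groups", call. = FALSE)
  ord <- order(rpkm, genes$gene_id)
  mid <- floor((N - n) / 2) + seq_len(n)
  list(inactive = genes$gene_id[ord[seq_len(n)]],
       middle = genes$gene_id[ord[mid]],
       active = genes$gene_id[ord[N - n + seq_len(n)]],
       n = n)
}

# per-gene promoter-anchored call table: one row per (call, gene) hit
.promoterCallHits <- function(calls, promoters) {
  ce <- .callEnds(calls)
  cl <- ce$calls
  res <- ce$resolution
  if (!nrow(cl))
    return(data.frame(call = integer(), gene_id = character(),
                      end = character()))
  ## bins per promoter, with gene ids
  perProm <- lapply(seq_along(promoters), function(i) {
    b <- .grToBins(promoters[i], res)
    data.table::data.table(bin_key = .binKey(b$chrom, b$bin),
      gene_id = S4Vectors::mcols(promoters)$gene_id[i])
  })
  lut <- unique(data.table::rbindlist(perProm))
  keys <- .callEndKeys(cl)
  hitA <- lut[match(keys$a, lut$bin_key), ]
  hitB <- lut[match(keys$b, lut$bin_key), ]
  oneEnd <- function(hit, label) {
    idx <- which(!is.na(hit$gene_id))
    data.frame(call = idx, gene_id = hit$gene_id[idx],
               end = rep(label, length(idx)), stringsAsFactors = FALSE)
  }
  if (is.null(lut$gene_id))
    return(data.frame(call = integer(), gene_id = character(),
                      end = character()))
  unique(rbind(oneEnd(hitA, "A"), oneEnd(hitB, "B")))
}

#' Share of promoter-anchored interactions per gene group
#'
#' Per-group percentage of all promoter-anchored calls, against the
#' expected share from an even distribution of interactions over genes
#' (the group's size share).
#'
#' @param calls an \linkS4class{InteractionCalls}.
#' @param promoters promoter \code{GRanges} with gene_id.
#' @param groups list of gene-id vectors (e.g. from
#'   \code{\link{expressionGroups}}).
#' @return data.frame with group, n_calls, share_pct, expected_pct.
#' @export
promoterInteractionStats <- function(calls, promoters, groups) {
  hits <- .promoterCallHits(calls, promoters)
  if (!nrow(hits)) stop("no promoter-anchored calls", call. = FALSE)
  nGenes <- length(unique(S4Vectors::mcols(promoters)$gene_id))
  perGene <- table(hits$gene_id)
  total <- sum(perGene)
  grpNames <- setdiff(names(groups), "n")
  do.call(rbind, lapply(grpNames, function(g) {
    ids <- groups[[g]]
    n <- sum(perGene[intersect(ids, names(perGene))])
    data.frame(group = g, n_calls = n,
               share_pct = 100 * n / total,
               expected_pct = 100 * length(ids) / nGenes,
               stringsAsFactors = FALSE)
  }))
}

#' Expression by promoter interaction-signal level
#'
#' Promoter interaction signal is the sum of anchored call scores; genes
#' are grouped into lowest/middle/highest signal groups (same scheme as
#' \code{\link{expressionGroups}}) and their expression distributions
#' compared by two-sided Wilcoxon rank-sum tests.
#'
#' @param calls scored \linkS4class{InteractionCalls}.
#' @param promoters promoter \code{GRanges} with gene_id.
#' @param genes gene table.
#' @param genotype rpkm column to compare.
#' @param fraction group-size fraction.
#' @return list with groups, per-group RPKM vectors and p-values
#'   (highest vs lowest, highest vs middle, middle vs lowest).
#' @export
expressionByInteractionLevel <- function(calls, promoters, genes,
                                         genotype, fraction = 0.05) {
  cl <- interactionCalls(calls)
  if (!"score" %in% names(cl))
    stop("calls must be scored", call. = FALSE)
  hits <- .promoterCallHits(calls, promoters)
  if (!nrow(hits)) stop("no promoter-anchored calls", call. = FALSE)
  sig <- setNames(rep(0, nrow(genes)), genes$gene_id)
  agg <- tapply(cl$score[hits$call], hits$gene_id, sum)
  sig[names(agg)] <- agg
  fake <- genes
  fake$signal <- sig[genes$gene_id]
  N <- nrow(fake); n <- round(fraction * N)
  if (n < 1L) stop("too few genes for the requested fraction",
                   call. = FALSE)
  ord <- order(fake$signal, fake$gene_id)
  mid <- floor((N - n) / 2) + seq_len(n)
  grp <- list(lowest = ord[seq_len(n)], middle = ord[mid],
              highest = ord[N - n + seq_len(n)])
  rpkm <- genes[[paste0("rpkm_", genotype)]]
  vals <- lapply(grp, function(i) rpkm[i])
  wt <- function(a, b) {
    if (identical(a, b)) return(1)
    n <- min(length(a), length(b))
    suppressWarnings(wilcox.test(a, b, exact = n < 20)$p.value)
  }
  list(rpkm = vals,
       p = c(highest_vs_lowest = wt(vals$highest, vals$lowest),
             highest_vs_middle = wt(vals$highest, vals$middle),
             middle_vs_lowest = wt(vals$middle, vals$lowest)),
       signal = sig)
}

#' Median expression of genes connected to each transcription factor
#'
#' A gene is connected to a TF iff some call joins the gene's promoter
#' to one of that TF's peaks. Reports per-TF medians for connected and
#' unconnected genes plus the genome-wide median.
#'
#' @param calls an \linkS4class{InteractionCalls}.
#' @param tfPeaks named list of peak \code{GRanges}, one per TF.
#' @param promoters promoter \code{GRanges} with gene_id.
#' @param genes gene table.
#' @param genotype rpkm column.
#' @return data.frame (tf, n_connected, median_connected,
#'   median_unconnected); genome-wide median as attribute
#'   \code{"genome_median"}.
#' @export
tfConnectedExpression <- function(calls, tfPeaks, promoters, genes,
                                  genotype) {
  ce <- .callEnds(calls)
  cl <- ce$calls
  res <- ce$resolution
  hits <- .promoterCallHits(calls, promoters)
  keys <- .callEndKeys(cl)
  rpkm <- setNames(genes[[paste0("rpkm_", genotype)]], genes$gene_id)
  rows <- list()
  for (tf in names(tfPeaks)) {
    pk <- tfPeaks[[tf]]
    if (!length(pk)) {
      warning("TF '", tf, "' has zero peaks; skipped")
      next
    }
    pb <- .grToBins(pk, res)
    pkKeys <- .binKey(pb$chrom, pb$bin)
    inPeakA <- keys$a %in% pkKeys
    inPeakB <- keys$b %in% pkKeys
    ## connected: the call's other (non-promoter) end is in a peak
    hitPeak <- ifelse(hits$end == "A", inPeakB[hits$call],
                      inPeakA[hits$call])
    connected <- unique(hits$gene_id[hitPeak])
    unconnected <- setdiff(genes$gene_id, connected)
    rows[[tf]] <- data.frame(
      tf = tf, n_connected = length(connected),
      median_connected = if (length(connected))
        median(rpkm[connected]) else NA_real_,
      median_unconnected = median(rpkm[unconnected]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "genome_median") <- median(rpkm)
  out
}

#' ChIP enrichment at distal regions looping to DE genes
#'
#' For calls above \code{scoreCutoff} with one end in the promoter of a
#' differentially expressed gene, takes the non-promoter (distal) end
#' and its per-bin ChIP enrichment (sample / control); distributions for
#' up- vs down-regulated gene sets are compared by a two-sided rank-sum
#' test. A region at or above \code{foldThreshold} counts as bound.
#'
#' @param calls scored \linkS4class{InteractionCalls}.
#' @param promoters promoter \code{GRanges} with gene_id.
#' @param deSets list with up and down gene-id vectors.
#' @param chipSample,chipControl \code{GRanges} signal tracks.
#' @param scoreCutoff minimum call score.
#' @param foldThreshold bound-site fold threshold (>= rule).
#' @return list with per-set enrichment vectors, bound fractions and
#'   the rank-sum p-value.
#' @export
distalChipEnrichment <- function(calls, promoters, deSets, chipSample,
                                 chipControl, scoreCutoff = 15,
                                 foldThreshold = 4) {
  cl <- interactionCalls(calls)
  if (!"score" %in% names(cl)) stop("calls must be scored", call. = FALSE)
  res <- binResolution(calls)
  keep <- cl$score >= scoreCutoff
  sub <- methods::initialize(calls, calls = cl[keep, , drop = FALSE])
  hits <- .promoterCallHits(sub, promoters)
  if (!nrow(hits)) stop("no qualifying promoter-anchored calls",
                        call. = FALSE)
  scl <- interactionCalls(sub)
  st <- .trackTable(chipSample, res)
  ct <- .trackTable(chipControl, res)
  sig <- merge(st, ct, by = c("chrom", "bin"), suffixes = c(".s", ".c"))
  sig$enr <- (sig$score.s + 0.5) / (sig$score.c + 0.5)
  sigKey <- .binKey(sig$chrom, sig$bin)
  promKeys <- unique(.binKey(.grToBins(promoters, res)$chrom,
                             .grToBins(promoters, res)$bin))
  distalEnr <- function(ids) {
    h <- hits[hits$gene_id %in% ids, , drop = FALSE]
    if (!nrow(h)) return(numeric())
    chrom <- ifelse(h$end == "A", scl$chromB[h$call], scl$chromA[h$call])
    bin <- ifelse(h$end == "A", scl$binB[h$call], scl$binA[h$call])
    key <- .binKey(chrom, bin)
    distal <- !(key %in% promKeys)
    as.numeric(stats::na.omit(sig$enr[match(unique(key[distal]),
                                            sigKey)]))
  }
  up <- distalEnr(deSets$up)
  down <- distalEnr(deSets$down)
  p <- if (length(up) && length(down))
    suppressWarnings(wilcox.test(up, down)$p.value) else NA_real_
  list(up = up, down = down,
       bound_up = mean(up >= foldThreshold),
       bound_down = mean(down >= foldThreshold),
       p.value = p)
}

#' TSS x DMR interaction surface with random-background subtraction
#'
#' Builds the summed interaction-signal matrix indexed by offset from a
#' TSS on one axis and offset from a DMR centre on the other: calls at
#' least \code{minDistance} apart contribute their score to every
#' (TSS offset, DMR offset) cell they support (cells accumulate the sum
#' of supporting scores, so planted contacts dominate isolated
#' background calls). The same procedure run against \code{nRandom}
#' size-matched random region sets gives a mean background surface that
#' is subtracted; a min-max scaled copy is also returned.
#'
#' @param calls scored \linkS4class{InteractionCalls} (or unscored;
#'   counts are used).
#' @param tss data.frame with gene_id, chrom, strand, tss.
#' @param dmrs \code{GRanges}.
#' @param genome a \linkS4class{HicGenome}.
#' @param minDistance minimum call separation in bp.
#' @param window half-window around TSS and DMR centre in bp (multiple
#'   of the call resolution).
#' @param nRandom number of random region sets (>= 10).
#' @param seed integer seed.
#' @param universe optional data.frame of permissible random-region
#'   bins (chrom, bin); defaults to non-centromeric bins.
#' @return list with matrix (background-subtracted), scaled (min-max),
#'   offsetsTss, offsetsDmr, nContributing.
#' @export
tssDmrSurface <- function(calls, tss, dmrs, genome, minDistance = 1e4,
                          window = 5000, nRandom = 10L, seed = 1L,
                          universe = NULL) {
  ce <- .callEnds(calls)
  cl <- ce$calls
  res <- ce$resolution
  if (window %% res != 0)
    stop("'window' must be a multiple of the call resolution",
         call. = FALSE)
  if (nRandom < 10L) stop("'nRandom' must be >= 10", call. = FALSE)
  k <- window / res
  offsets <- seq(-k, k) * res
  val <- if ("score" %in% names(cl)) cl$score else cl$count
  intra <- cl$chromA == cl$chromB
  far <- intra & (abs(cl$binB - cl$binA) * res >= minDistance)
  cl <- cl[far, , drop = FALSE]
  val <- val[far]

  dims <- c(length(offsets), length(offsets))
  accumulate <- function(centers) {
    ## centers: data.frame(chrom, pos, sign) of region centres
    m <- matrix(0, dims[1], dims[2])
    cnt <- matrix(0, dims[1], dims[2])
    if (!nrow(cl)) return(list(sum = m, n = cnt))
    for (side in c("AB", "BA")) {
      tssEnd <- if (side == "AB") list(ch = cl$chromA, b = cl$binA)
                else list(ch = cl$chromB, b = cl$binB)
      othEnd <- if (side == "AB") list(ch = cl$chromB, b = cl$binB)
                else list(ch = cl$chromA, b = cl$binA)
      tssPos <- tssEnd$b * res + res / 2
      othPos <- othEnd$b * res + res / 2
      for (i in seq_len(nrow(tss))) {
        selT <- tssEnd$ch == tss$chrom[i] &
          abs(tssPos - tss$tss[i]) <= window
        if (!any(selT)) next
        sgn <- if (tss$strand[i] == "+") 1 else -1
        offT <- (tssPos[selT] - tss$tss[i]) * sgn
        for (j in seq_len(nrow(centers))) {
          selD <- othEnd$ch[selT] == centers$chrom[j] &
            abs(othPos[selT] - centers$pos[j]) <= window
          if (!any(selD)) next
          offD <- othPos[selT][selD] - centers$pos[j]
          it <- round(offT[selD] / res) + k + 1
          id <- round(offD / res) + k + 1
          vsel <- val[selT][selD]
          for (q in seq_along(it)) {
            m[it[q], id[q]] <- m[it[q], id[q]] + vsel[q]
            cnt[it[q], id[q]] <- cnt[it[q], id[q]] + 1
          }
        }
      }
    }
    list(sum = m, n = cnt)
  }
  dmrCenters <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dmrs)),
    pos = (GenomicRanges::start(dmrs) + GenomicRanges::end(dmrs)) / 2,
    stringsAsFactors = FALSE)
  obs <- accumulate(dmrCenters)
  obsSum <- obs$sum

  ## random background: size-matched random centres from the universe
  if (is.null(universe)) {
    cs <- chromSizes(genome)
    grid <- data.table::rbindlist(lapply(names(cs), function(ch)
      data.table::data.table(chrom = ch,
        bin = seq_len(cs[[ch]] %/% res) - 1L)))
    cenBins <- .grToBins(centromeres(genome), res)
    grid <- grid[!.binKey(grid$chrom, grid$bin) %in%
                   .binKey(cenBins$chrom, cenBins$bin)]
    universe <- grid
  }
  set.seed(as.integer(seed))
  bg <- matrix(0, dims[1], dims[2])
  for (r in seq_len(nRandom)) {
    idx <- sample.int(nrow(universe), nrow(dmrCenters))
    rc <- data.frame(chrom = universe$chrom[idx],
                     pos = universe$bin[idx] * res + res / 2)
    rr <- accumulate(rc)
    bg <- bg + rr$sum
  }
  bg <- bg / nRandom
  out <- obsSum - bg
  rng <- range(out)
  scaled <- if (diff(rng) > 0) (out - rng[1]) / diff(rng) else out * 0
  nContrib <- sum(obs$n)
  if (nContrib == 0)
    warning("no qualifying TSS-DMR interactions; surface is background only")
  list(matrix = out, scaled = scaled, offsetsTss = offsets,
       offsetsDmr = offsets, nContributing = nContrib)
}

#' Genes connected to DMRs per genotype, with random-gene control
#'
#' Counts genes whose promoter is joined to a DMR by a call with score
#' at or above \code{scoreCutoff}, per genotype, as a ratio to the
#' wild-type count; the same statistic on size-matched random gene sets
#' is the control.
#'
#' @param callsByGenotype named list of scored calls.
#' @param genes gene table (the gene set of interest).
#' @param allGenes full gene table for drawing random sets.
#' @param dmrs \code{GRanges}.
#' @param genome a \linkS4class{HicGenome}.
#' @param scoreCutoff minimum score (>= rule).
#' @param wildType wild-type sample name.
#' @param nRandomSets number of random gene sets.
#' @param seed integer seed.
#' @return list with counts, ratios, the random-set mean ratios and
#'   mean counts, and a flag for an undefined (zero) wild-type
#'   denominator.
#' @export
geneDmrConnections <- function(callsByGenotype, genes, allGenes, dmrs,
                               genome, scoreCutoff = 5,
                               wildType = "Col0", nRandomSets = 10L,
                               seed = 1L) {
  if (!nrow(genes)) stop("empty gene set", call. = FALSE)
  res <- binResolution(callsByGenotype[[1L]])
  dmrB <- .grToBins(dmrs, res)
  dmrKeys <- unique(.binKey(dmrB$chrom, dmrB$bin))
  countConnected <- function(geneSet, callsObj) {
    cl <- interactionCalls(callsObj)
    cl <- cl[cl$score >= scoreCutoff, , drop = FALSE]
    sub <- methods::initialize(callsObj, calls = cl)
    proms <- definePromoters(geneSet, genome)
    hits <- .promoterCallHits(sub, proms)
    if (!nrow(hits)) return(0L)
    keys <- .callEndKeys(cl)
    otherKey <- ifelse(hits$end == "A", keys$b[hits$call],
                       keys$a[hits$call])
    length(unique(hits$gene_id[otherKey %in% dmrKeys]))
  }
  counts <- vapply(callsByGenotype, function(co)
    countConnected(genes, co), numeric(1))
  wtN <- counts[[wildType]]
  ratios <- if (wtN > 0) counts / wtN else
    setNames(rep(NA_real_, length(counts)), names(counts))

  set.seed(as.integer(seed))
  randRatios <- matrix(NA_real_, nrow = nRandomSets,
                       ncol = length(callsByGenotype),
                       dimnames = list(NULL, names(callsByGenotype)))
  randCounts <- randRatios
  for (r in seq_len(nRandomSets)) {
    idx <- sample.int(nrow(allGenes), nrow(genes))
    rg <- allGenes[idx, , drop = FALSE]
    rc <- vapply(callsByGenotype, function(co)
      countConnected(rg, co), numeric(1))
    randCounts[r, ] <- rc
    if (rc[[wildType]] > 0) randRatios[r, ] <- rc / rc[[wildType]]
  }
  list(counts = counts, ratios = ratios,
       randomRatios = colMeans(randRatios, na.rm = TRUE),
       randomCounts = colMeans(randCounts),
       wildTypeUndefined = wtN == 0)
}

#' Fold-change distributions for DMR-connected vs unconnected genes
#'
#' Splits genes by the sign of their expression fold change and, within
#' each stratum, compares the fold changes of genes with and without a
#' DMR connection by a two-sided rank-sum test.
#'
#' @param connected logical per gene.
#' @param log2fc numeric per gene.
#' @return list with per-stratum results (values and p).
#' @export
deDirectionSplit <- function(connected, log2fc) {
  out <- list()
  for (s in c("positive", "negative")) {
    sel <- if (s == "positive") log2fc > 0 else log2fc < 0
    co <- log2fc[sel & connected]
    un <- log2fc[sel & !connected]
    if (!length(co) || !length(un)) {
      warning(s, " stratum has an empty group; comparison skipped")
      out[[s]] <- list(connected = co, unconnected = un, p = NA_real_)
      next
    }
    out[[s]] <- list(connected = co, unconnected = un,
                     p = suppressWarnings(wilcox.test(co, un)$p.value))
  }
  out
}

#' AGO4 localization classes for interacting genes
#'
#' For genes with promoter-anchored calls, distal ends qualifying as
#' distal regulatory regions (at least \code{minSites} restriction
#' sites away from the gene body plus its promoter) are inspected for
#' AGO4 peaks, as is the promoter. Genes with AGO4 anywhere are
#' classified promoter-only, distal-only or both.
#'
#' @param calls an \linkS4class{InteractionCalls}.
#' @param genes gene table (must include start/end body columns).
#' @param ago4 AGO4 peak \code{GRanges}.
#' @param genome a \linkS4class{HicGenome}.
#' @param minSites minimum restriction-site separation (>= rule).
#' @return list with counts per class and the per-gene table.
#' @export
ago4LocalizationClasses <- function(calls, genes, ago4, genome,
                                    minSites = 3L) {
  res <- binResolution(calls)
  proms <- definePromoters(genes, genome)
  hits <- .promoterCallHits(calls, proms)
  cl <- interactionCalls(calls)
  keys <- .callEndKeys(cl)
  ago4Bins <- .grToBins(ago4, res)
  ago4Keys <- unique(.binKey(ago4Bins$chrom, ago4Bins$bin))
  promByGene <- split(seq_along(proms),
                      S4Vectors::mcols(proms)$gene_id)
  rows <- list()
  for (gid in unique(hits$gene_id)) {
    g <- genes[genes$gene_id == gid, ]
    h <- hits[hits$gene_id == gid, , drop = FALSE]
    ## gene region = body union promoter, as 0-based [lo, hi)
    pr <- proms[promByGene[[gid]]]
    lo <- min(g$start, GenomicRanges::start(pr) - 1L)
    hi <- max(g$end, GenomicRanges::end(pr))
    chrom <- ifelse(h$end == "A", cl$chromB[h$call], cl$chromA[h$call])
    bin <- ifelse(h$end == "A", cl$binB[h$call], cl$binA[h$call])
    pos <- bin * res + res / 2
    sameChrom <- chrom == g$chrom
    nearEdge <- pmin(abs(pos - lo), abs(pos - hi))
    nSites <- rep(Inf, length(pos))  # other chromosome: trivially distal
    if (any(sameChrom)) {
      inside <- sameChrom & pos >= lo & pos < hi
      edge <- ifelse(pos < lo, lo, hi)
      nSites[sameChrom] <- sitesBetween(genome, g$chrom,
                                        pos[sameChrom],
                                        edge[sameChrom])
      nSites[inside] <- 0
    }
    distalOk <- nSites >= minSites
    distalKeys <- unique(.binKey(chrom[distalOk], bin[distalOk]))
    ago4Distal <- any(distalKeys %in% ago4Keys)
    ago4Prom <- any(IRanges::overlapsAny(pr, ago4))
    class <- if (ago4Prom && ago4Distal) "both"
             else if (ago4Prom) "promoter_only"
             else if (ago4Distal) "distal_only" else "none"
    rows[[gid]] <- data.frame(gene_id = gid, class = class,
                              n_distal = sum(distalOk),
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), class = character(),
                      n_distal = integer())
  withAgo <- tab[tab$class != "none", , drop = FALSE]
  counts <- c(promoter_only = sum(withAgo$class == "promoter_only"),
              distal_only = sum(withAgo$class == "distal_only"),
              both = sum(withAgo$class == "both"))
  list(counts = counts, genes = tab)
}

#' Distances from TSSs to the nearest upstream peak
#'
#' Strand-aware upstream search: for each gene, the gap in bp between
#' the TSS and the closest peak edge upstream of it (0 when the peak
#' abuts the TSS). Genes without any upstream peak are censored and
#' excluded from the histogram.
#'
#' @param genes gene table.
#' @param peaks \code{GRanges}.
#' @param cutoff promoter-proximity cutoff in bp.
#' @return list with distances (named by gene), fraction_within
#'   (of non-censored genes with distance <= cutoff over all genes),
#'   log2_hist and n_censored.
#' @export
upstreamPeakDistances <- function(genes, peaks, cutoff = 2500) {
  pk <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    s0 = GenomicRanges::start(peaks) - 1L,
    e0 = GenomicRanges::end(peaks))
  d <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    onChr <- pk[pk$chrom == genes$chrom[i], , drop = FALSE]
    if (!nrow(onChr)) next
    t <- genes$tss[i]
    if (genes$strand[i] == "+") {
      up <- onChr[onChr$e0 <= t, , drop = FALSE]
      if (nrow(up)) d[i] <- t - max(up$e0)
    } else {
      up <- onChr[onChr$s0 >= t + 1L, , drop = FALSE]
      if (nrow(up)) d[i] <- min(up$s0) - t - 1L
    }
  }
  names(d) <- genes$gene_id
  obs <- d[!is.na(d)]
  list(distances = d,
       fraction_within = sum(obs <= cutoff) / nrow(genes),
       log2_hist = if (length(obs)) hist(log2(obs + 1), plot = FALSE)
                   else NULL,
       n_censored = sum(is.na(d)))
}

#' Distance and orientation of promoter-DMR calls relative to the TSS
#'
#' For calls joining a promoter and a DMR, reports the signed distance
#' from the TSS to the DMR end in transcription coordinates (positive =
#' upstream of the TSS) and tests the upstream/downstream split against
#' 0.5.
#'
#' @param calls an \linkS4class{InteractionCalls}.
#' @param genes gene table.
#' @param dmrs \code{GRanges}.
#' @param genome a \linkS4class{HicGenome}.
#' @return list with a per-call table (gene_id, distance_bp,
#'   signed_distance, orientation), the upstream fraction and a
#'   two-sided binomial p-value.
#' @export
dmrGeneDistanceOrientation <- function(calls, genes, dmrs, genome) {
  res <- binResolution(calls)
  proms <- definePromoters(genes, genome)
  hits <- .promoterCallHits(calls, proms)
  cl <- interactionCalls(calls)
  dmrB <- .grToBins(dmrs, res)
  dmrKeys <- unique(.binKey(dmrB$chrom, dmrB$bin))
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    g <- genes[genes$gene_id == hits$gene_id[i], ]
    chrom <- if (hits$end[i] == "A") cl$chromB[hits$call[i]]
             else cl$chromA[hits$call[i]]
    bin <- if (hits$end[i] == "A") cl$binB[hits$call[i]]
           else cl$binA[hits$call[i]]
    if (!.binKey(chrom, bin) %in% dmrKeys || chrom != g$chrom) next
    pos <- bin * res + res / 2
    signed <- (g$tss - pos) * if (g$strand == "+") 1 else -1
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g$gene_id, distance_bp = abs(pos - g$tss),
      signed_distance = signed,
      orientation = if (signed >= 0) "upstream" else "downstream",
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(list(table = data.frame(), upstream_fraction = NA_real_,
                p = NA_real_))
  upFrac <- mean(tab$orientation == "upstream")
  p <- stats::binom.test(sum(tab$orientation == "upstream"),
                         nrow(tab))$p.value
  list(table = tab, upstream_fraction = upFrac, p = p)
}
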