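## S4 classes for the central data objects.

#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Genome skeleton with restriction map and centromere/telomere masks
#'
#' A \code{HicGenome} holds everything positional the pipeline needs:
#' chromosome sizes, the sorted restriction cut-site map per chromosome
#' (0-based coordinates, as for a 4-cutter digest), and centromere and
#' telomere interval masks.
#'
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @slot restrictionSites named list of strictly increasing integer vectors
#'   of 0-based cut positions, one per chromosome.
#' @slot centromeres,telomeres \code{GRanges} masks.
#'
#' @aliases HicGenome
#' @exportClass HicGenome
setClass("HicGenome",
  representation(chromSizes = "integer",
                 restrictionSites = "list",
                 centromeres = "GRanges",
                 telomeres = "GRanges"))

setValidity("HicGenome", function(object) {
  msg <- character()
  cs <- object@chromSizes
  if (is.null(names(cs)) || anyDuplicated(names(cs)))
    msg <- c(msg, "chromSizes must be uniquely named")
  if (any(cs <= 0L)) msg <- c(msg, "chromosome lengths must be positive")
  if (!setequal(names(object@restrictionSites), names(cs)))
    msg <- c(msg, "restrictionSites must cover exactly the chromosomes")
  for (chrom in names(object@restrictionSites)) {
    s <- object@restrictionSites[[chrom]]
    if (length(s)) {
      if (is.unsorted(s, strictly = TRUE))
        msg <- c(msg, sprintf("sites on %s not strictly increasing", chrom))
      if (min(s) < 0L || max(s) >= cs[[chrom]])
        msg <- c(msg, sprintf("sites on %s outside [0, length)", chrom))
    }
  }
  for (nm in c("centromeres", "telomeres")) {
    gr <- slot(object, nm)
    if (length(gr)) {
      chr <- as.character(GenomicRanges::seqnames(gr))
      if (!all(chr %in% names(cs)))
        msg <- c(msg, sprintf("%s on unknown chromosome", nm))
      else if (any(GenomicRanges::end(gr) > cs[chr]))
        msg <- c(msg, sprintf("%s beyond chromosome bounds", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Planted-loop ledger for the synthetic generator
#'
#' Records the structure planted into simulated Hi-C read pairs: loop
#' anchors with per-genotype intensity multipliers, plus regions whose
#' background contacts are thinned per genotype (modelling RdDM-mediated
#' suppression of contacts in wild-type). Downstream recovery is scored
#' against this ledger.
#'
#' @slot anchorA,anchorB \code{GRanges}, one range per planted loop.
#' @slot intensity numeric matrix, loops x genotypes; multiplier >= 0.
#' @slot loopType character per loop, e.g. \code{"rddm"} or
#'   \code{"expression"}.
#' @slot suppression \code{GRanges} of thinned regions.
#' @slot retention numeric matrix, suppression regions x genotypes; the
#'   probability that a background pair with an end in the region is kept.
#' @slot genotypes character vector of genotype names.
#' @slot wildType name of the wild-type genotype.
#'
#' @aliases SyntheticTruth
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(anchorA = "GRanges", anchorB = "GRanges",
                 intensity = "matrix", loopType = "character",
                 suppression = "GRanges", retention = "matrix",
                 genotypes = "character", wildType = "character"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  n <- length(object@anchorA)
  if (length(object@anchorB) != n || length(object@loopType) != n ||
      nrow(object@intensity) != n)
    msg <- c(msg, "anchorA, anchorB, loopType, intensity rows must align")
  if (!identical(colnames(object@intensity), object@genotypes))
    msg <- c(msg, "intensity columns must be the genotypes")
  if (n && (!all(is.finite(object@intensity)) || any(object@intensity < 0)))
    msg <- c(msg, "intensity multipliers must be finite and >= 0")
  if (n) {
    allAnchors <- c(object@anchorA, object@anchorB)
    if (sum(IRanges::countOverlaps(allAnchors, allAnchors) > 1L) > 0L)
      msg <- c(msg, "loop anchors must not overlap each other")
  }
  if (!(object@wildType %in% object@genotypes))
    msg <- c(msg, "wildType must be one of the genotypes")
  if (n && "rddm" %in% object@loopType) {
    rd <- object@loopType == "rddm"
    wt <- object@intensity[rd, object@wildType, drop = FALSE]
    mut <- object@intensity[rd, setdiff(object@genotypes, object@wildType),
                            drop = FALSE]
    if (ncol(mut) && any(wt > apply(mut, 1L, min)))
      msg <- c(msg, "wild-type multiplier at RdDM loops must be <= mutant")
  }
  if (nrow(object@retention) != length(object@suppression))
    msg <- c(msg, "retention rows must match suppression regions")
  if (length(object@retention) &&
      (any(object@retention < 0) || any(object@retention > 1)))
    msg <- c(msg, "retention probabilities must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic chromatin, methylation and expression tracks
#'
#' Bundles the bedGraph-style tracks and feature sets the enrichment and
#' gene-looping modules consume: per-context methylation fractions per
#' genotype, H3K4me2/H3K9me2, a decrosslinked-control coverage track,
#' ChIP sample/control signal, an MNase wild-type/mutant ratio track,
#' feature interval sets (DMRs, other high-CHH regions, AGO4 and TF
#' peaks), and a per-gene expression table.
#'
#' @slot tracks named list of \code{GRanges} with a \code{score} column.
#' @slot features named list of \code{GRanges}.
#' @slot genes data.frame with gene_id, chrom, strand, tss, start, end,
#'   one rpkm_<genotype> column per genotype, de_label, log2fc.
#' @slot genotypes character vector of genotype names.
#'
#' @aliases TrackBundle
#' @exportClass TrackBundle
setClass("TrackBundle",
  representation(tracks = "list", features = "list",
                 genes = "data.frame", genotypes = "character"))

setValidity("TrackBundle", function(object) {
  msg <- character()
  methNames <- grep("^me(CG|CHG|CHH)\\.", names(object@tracks), value = TRUE)
  for (nm in methNames) {
    sc <- object@tracks[[nm]]$score
    if (length(sc) && (min(sc) < 0 || max(sc) > 1))
      msg <- c(msg, sprintf("%s fractions must lie in [0,1]", nm))
  }
  g <- object@genes
  if (nrow(g)) {
    rpkmCols <- grep("^rpkm_", names(g), value = TRUE)
    for (cc in rpkmCols)
      if (any(g[[cc]] < 0)) msg <- c(msg, "RPKM must be >= 0")
    if (!all(g$strand %in% c("+", "-")))
      msg <- c(msg, "every gene needs a strand")
    if (any(is.na(g$tss))) msg <- c(msg, "every gene needs a TSS")
  }
  if (length(msg)) msg else TRUE
})

#' Binned Hi-C contacts
#'
#' Counts of read pairs connecting two fixed-width genomic bins, the
#' universal contact currency of the pipeline. Bin indices are
#' \code{floor(pos / resolution)} on 0-based positions and bin pairs are
#' canonically ordered.
#'
#' @slot counts data.frame with chromA, binA, chromB, binB, count and
#'   optionally replicate.
#' @slot resolution bin width in bp.
#' @slot nPairs total read pairs that went into the binning.
#'
#' @aliases BinnedContacts
#' @exportClass BinnedContacts
setClass("BinnedContacts",
  representation(counts = "data.frame", resolution = "numeric",
                 nPairs = "numeric"))

setValidity("BinnedContacts", function(object) {
  msg <- character()
  cts <- object@counts
  need <- c("chromA", "binA", "chromB", "binB", "count")
  if (!all(need %in% names(cts)))
    msg <- c(msg, "counts must have chromA, binA, chromB, binB, count")
  else {
    if (nrow(cts) && any(cts$count < 1L))
      msg <- c(msg, "counts must be >= 1")
    if (nrow(cts)) {
      bad <- cts$chromA > cts$chromB |
        (cts$chromA == cts$chromB & cts$binA > cts$binB)
      if (any(bad)) msg <- c(msg, "bin pairs must be canonically ordered")
    }
  }
  if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
  if (length(msg)) msg else TRUE
})

#' Called chromosomal interactions
#'
#' Bin pairs surviving an interaction caller, carrying read count and
#' (for the simple caller) the interaction score. \code{method} is
#' \code{"simple"} or \code{"stringent"}; stringent calls additionally
#' carry expected counts, p-values and an FDR flag.
#'
#' @slot calls data.frame of surviving bin pairs.
#' @slot resolution bin width in bp.
#' @slot method caller tag.
#' @slot sample sample/genotype label.
#' @slot settings list of caller settings (threshold etc.).
#'
#' @aliases InteractionCalls
#' @exportClass InteractionCalls
setClass("InteractionCalls",
  representation(calls = "data.frame", resolution = "numeric",
                 method = "character", sample = "character",
                 settings = "list"))

setValidity("InteractionCalls", function(object) {
  msg <- character()
  cl <- object@calls
  if (!object@method %in% c("simple", "stringent"))
    msg <- c(msg, "method must be 'simple' or 'stringent'")
  if (nrow(cl)) {
    if (object@method == "simple") {
      if (any(cl$count < 2L))
        msg <- c(msg, "simple calls need count >= 2")
      intra <- cl$chromA == cl$chromB
      minD <- object@settings$minDistance
      if (!is.null(minD) && any(intra & abs(cl$binB - cl$binA) < minD))
        msg <- c(msg, "intra-chromosomal simple calls closer than minimum")
      if ("score" %in% names(cl) && any(cl$score <= 0))
        msg <- c(msg, "scores must be positive")
    }
    if (object@method == "stringent") {
      if (any(cl$chromA != cl$chromB))
        msg <- c(msg, "stringent calls are intra-chromosomal only")
      if (any(cl$pvalue <= 0 | cl$pvalue > 1))
        msg <- c(msg, "p-values must lie in (0,1]")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn HicGenome chromosome sizes (named integer vector)
#' @param object a \code{HicGenome}
#' @export
setGeneric("chromSizes", function(object) standardGeneric("chromSizes"))
#' @export
setMethod("chromSizes", "HicGenome", function(object) object@chromSizes)

#' @describeIn HicGenome restriction cut sites (named list, 0-based)
#' @export
setGeneric("restrictionSites",
           function(object) standardGeneric("restrictionSites"))
#' @export
setMethod("restrictionSites", "HicGenome",
          function(object) object@restrictionSites)

#' @describeIn HicGenome centromere mask
#' @export
setGeneric("centromeres", function(object) standardGeneric("centromeres"))
#' @export
setMethod("centromeres", "HicGenome", function(object) object@centromeres)

#' @describeIn HicGenome telomere mask
#' @export
setGeneric("telomeres", function(object) standardGeneric("telomeres"))
#' @export
setMethod("telomeres", "HicGenome", function(object) object@telomeres)

#' Contact counts table
#' @param object a \code{BinnedContacts} or \code{InteractionCalls}
#' @export
setGeneric("contactCounts", function(object) standardGeneric("contactCounts"))
#' @export
setMethod("contactCounts", "BinnedContacts", function(object) object@counts)

#' Bin resolution in bp
#' @param object an object with a bin resolution
#' @export
setGeneric("binResolution", function(object) standardGeneric("binResolution"))
#' @export
setMethod("binResolution", "BinnedContacts", function(object) object@resolution)
#' @export
setMethod("binResolution", "InteractionCalls",
          function(object) object@resolution)

#' Calls table of an \code{InteractionCalls} object
#' @param object an \code{InteractionCalls}
#' @export
setGeneric("interactionCalls",
           function(object) standardGeneric("interactionCalls"))
#' @export
setMethod("interactionCalls", "InteractionCalls", function(object) object@calls)

#' Caller method tag ("simple" or "stringent")
#' @param object an \code{InteractionCalls}
#' @export
setGeneric("callerMethod", function(object) standardGeneric("callerMethod"))
#' @export
setMethod("callerMethod", "InteractionCalls", function(object) object@method)

#' Caller settings list
#' @param object an \code{InteractionCalls}
#' @export
setGeneric("callerSettings", function(object) standardGeneric("callerSettings"))
#' @export
setMethod("callerSettings", "InteractionCalls",
          function(object) object@settings)

#' Synthetic-truth accessors
#' @param object a \code{SyntheticTruth}
#' @export
setGeneric("plantedLoops", function(object) standardGeneric("plantedLoops"))
#' @export
setMethod("plantedLoops", "SyntheticTruth", function(object) {
  data.frame(
    chromA = as.character(GenomicRanges::seqnames(object@anchorA)),
    startA = GenomicRanges::start(object@anchorA) - 1L,
    endA   = GenomicRanges::end(object@anchorA),
    chromB = as.character(GenomicRanges::seqnames(object@anchorB)),
    startB = GenomicRanges::start(object@anchorB) - 1L,
    endB   = GenomicRanges::end(object@anchorB),
    loop_type = object@loopType,
    object@intensity,
    check.names = FALSE, stringsAsFactors = FALSE)
})

#' Genotype names of a synthetic object
#' @param object a \code{SyntheticTruth} or \code{TrackBundle}
#' @export
setGeneric("genotypeNames", function(object) standardGeneric("genotypeNames"))
#' @export
setMethod("genotypeNames", "SyntheticTruth", function(object) object@genotypes)
#' @export
setMethod("genotypeNames", "TrackBundle", function(object) object@genotypes)

#' Track and feature accessors for a \code{TrackBundle}
#' @param object a \code{TrackBundle}
#' @param name track or feature name
#' @export
setGeneric("getTrack", function(object, name) standardGeneric("getTrack"))
#' @export
setMethod("getTrack", "TrackBundle", function(object, name) {
  if (!name %in% names(object@tracks))
    stop("unknown track: ", name, call. = FALSE)
  object@tracks[[name]]
})

#' @rdname getTrack
#' @export
setGeneric("getFeature", function(object, name) standardGeneric("getFeature"))
#' @export
setMethod("getFeature", "TrackBundle", function(object, name) {
  if (!name %in% names(object@features))
    stop("unknown feature set: ", name, call. = FALSE)
  object@features[[name]]
})

#' @rdname getTrack
#' @export
setGeneric("geneTable", function(object) standardGeneric("geneTable"))
#' @export
setMethod("geneTable", "TrackBundle", function(object) object@genes)

## ---- show ------------------------------------------------------------------

setMethod("show", "HicGenome", function(object) {
  cat("HicGenome with", length(object@chromSizes), "chromosomes,",
      format(sum(object@chromSizes), big.mark = ","), "bp total\n")
  cat("  restriction sites:",
      format(sum(lengths(object@restrictionSites)), big.mark = ","), "\n")
  cat("  centromeres:", length(object@centromeres),
      " telomeres:", length(object@telomeres), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  tab <- table(object@loopType)
  cat("SyntheticTruth:", length(object@anchorA), "planted loops (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "),", length(object@suppression), "suppressed regions\n")
  cat("  genotypes:", paste(object@genotypes, collapse = ", "),
      "(wild-type:", object@wildType, ")\n")
})

setMethod("show", "TrackBundle", function(object) {
  cat("TrackBundle:", length(object@tracks), "tracks,",
      length(object@features), "feature sets,",
      nrow(object@genes), "genes\n")
})

setMethod("show", "BinnedContacts", function(object) {
  cat("BinnedContacts at", object@resolution, "bp:",
      nrow(object@counts), "bin pairs,",
      format(object@nPairs, big.mark = ","), "read pairs\n")
})

setMethod("show", "InteractionCalls", function(object) {
  cat("InteractionCalls (", object@method, ") for sample '",
      object@sample, "': ", nrow(object@calls), " calls at ",
      object@resolution, " bp\n", sep = "")
})
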