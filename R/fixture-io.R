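## Plain-text fixture emission and re-loading (BED / bedGraph / TSV).
## On-disk interval formats follow BED conventions: 0-based, half-open.

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  nrow(x)
}

.grToBed <- function(gr, extra = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  df
}

.writeBed <- function(gr, path, name = "feature") {
  df <- .grToBed(gr)
  df$name <- sprintf("%s_%d", name, seq_len(nrow(df)))
  df$score <- if ("mnase_reduced" %in%
                  names(S4Vectors::mcols(gr)))
    as.integer(S4Vectors::mcols(gr)$mnase_reduced) else 0L
  df$strand <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  nrow(df)
}

.writeBedGraph <- function(gr, path) {
  df <- .grToBed(gr, extra = data.frame(score =
    S4Vectors::mcols(gr)$score))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  nrow(df)
}

#' Read a BED file into a GRanges
#'
#' Expects at least chrom/start/end; a fourth and further columns are kept
#' as name/score/strand metadata when present.
#' @param path BED file path.
#' @return \code{GRanges} (1-based internally).
#' @export
readBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df[[2]] >= df[[3]]))
    stop("BED intervals must satisfy start < end", call. = FALSE)
  gr <- .toGRanges(df[[1]], as.integer(df[[2]]), as.integer(df[[3]]))
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- df[[5]]
  if (ncol(df) >= 6 && all(df[[6]] %in% c("+", "-")))
    GenomicRanges::strand(gr) <- df[[6]]
  gr
}

#' Read a bedGraph track into a GRanges with a score column
#' @param path bedGraph file path.
#' @return \code{GRanges} with numeric \code{score}.
#' @export
readBedGraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "score"))
  gr <- .toGRanges(df$chrom, as.integer(df$start), as.integer(df$end))
  S4Vectors::mcols(gr)$score <- as.numeric(df$score)
  gr
}

#' Write the complete synthetic fixture to a directory
#'
#' Emits every generated object as small plain-text files: chromosome
#' sizes and restriction sites, centromere/telomere masks and feature
#' sets as BED, tracks as bedGraph, the gene/expression table and the
#' planted-loop truth ledger as TSV, and read pairs per genotype as a
#' 7-column tab-separated table. A manifest lists every file with its row
#' count.
#'
#' @param outdir output directory (created if missing).
#' @param genome a \linkS4class{HicGenome}.
#' @param tracks optional \linkS4class{TrackBundle}.
#' @param truth optional \linkS4class{SyntheticTruth}.
#' @param pairs named list (by genotype) of read-pair tables.
#' @return invisibly, the manifest data.frame (file, rows).
#' @export
writeFixture <- function(outdir, genome, tracks = NULL, truth = NULL,
                         pairs = list()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  probe <- file.path(outdir, ".write-test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("directory not writable: ", outdir, call. = FALSE)
  unlink(probe)

  manifest <- list()
  add <- function(file, rows) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = file, rows = rows, stringsAsFactors = FALSE)

  cs <- data.frame(chrom = names(chromSizes(genome)),
                   length = as.integer(chromSizes(genome)))
  add("chrom_sizes.tsv", .writeTsv(cs, file.path(outdir, "chrom_sizes.tsv")))

  sites <- data.table::rbindlist(lapply(names(restrictionSites(genome)),
    function(chrom) data.table::data.table(
      chrom = chrom, start = restrictionSites(genome)[[chrom]],
      end = restrictionSites(genome)[[chrom]] + 1L)))
  write.table(sites, file.path(outdir, "restriction_sites.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  add("restriction_sites.bed", nrow(sites))

  add("centromeres.bed", .writeBed(centromeres(genome),
      file.path(outdir, "centromeres.bed"), "centromere"))
  add("telomeres.bed", .writeBed(telomeres(genome),
      file.path(outdir, "telomeres.bed"), "telomere"))

  if (!is.null(tracks)) {
    for (nm in names(tracks@features))
      add(paste0("features_", nm, ".bed"),
          .writeBed(tracks@features[[nm]],
                    file.path(outdir, paste0("features_", nm, ".bed")), nm))
    for (nm in names(tracks@tracks))
      add(paste0("track_", nm, ".bedGraph"),
          .writeBedGraph(tracks@tracks[[nm]],
            file.path(outdir, paste0("track_", nm, ".bedGraph"))))
    add("expression.tsv",
        .writeTsv(geneTable(tracks), file.path(outdir, "expression.tsv")))
  }

  if (!is.null(truth)) {
    add("truth_loops.tsv",
        .writeTsv(plantedLoops(truth), file.path(outdir, "truth_loops.tsv")))
    supp <- .grToBed(truth@suppression)
    supp <- cbind(supp, as.data.frame(truth@retention))
    add("truth_suppression.tsv",
        .writeTsv(supp, file.path(outdir, "truth_suppression.tsv")))
  }

  for (g in names(pairs)) {
    f <- paste0("pairs_", g, ".tsv")
    data.table::fwrite(pairs[[g]], file.path(outdir, f), sep = "\t")
    add(f, nrow(pairs[[g]]))
  }

  manifest <- do.call(rbind, manifest)
  .writeTsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a fixture genome back from disk
#' @param dir fixture directory written by \code{\link{writeFixture}}.
#' @return a \linkS4class{HicGenome}.
#' @export
readGenomeFixture <- function(dir) {
  cs <- read.table(file.path(dir, "chrom_sizes.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  sizes <- setNames(as.integer(cs$length), cs$chrom)
  sb <- read.table(file.path(dir, "restriction_sites.bed"), sep = "\t",
                   stringsAsFactors = FALSE)
  sites <- lapply(split(as.integer(sb[[2]]), sb[[1]]), sort)
  sites <- setNames(lapply(names(sizes), function(ch)
    if (is.null(sites[[ch]])) integer(0) else sites[[ch]]), names(sizes))
  methods::new("HicGenome", chromSizes = sizes, restrictionSites = sites,
               centromeres = readBed(file.path(dir, "centromeres.bed")),
               telomeres = readBed(file.path(dir, "telomeres.bed")))
}
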