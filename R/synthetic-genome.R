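#' Generate a synthetic multi-chromosome genome with a restriction map
#'
#' Builds a genome skeleton emulating a small plant genome digested with a
#' 4-base-cutter: chromosome sizes, a seeded homogeneous point process of
#' restriction cut sites (a 4-cutter lands about every 256 bp, i.e. roughly
#' 4 sites per kb), a central centromere mask and telomere masks at both
#' chromosome ends.
#'
#' @param nChroms number of chromosomes (>= 1).
#' @param chromLength chromosome length in bp (>= 10 kb). Either a single
#'   value recycled to all chromosomes or one per chromosome.
#' @param siteDensity expected restriction sites per kb (> 0).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param centromereFraction fraction of each chromosome covered by the
#'   central centromere mask.
#' @param telomereLength length in bp of each telomere mask.
#'
#' @return a \linkS4class{HicGenome}.
#' @examples
#' gn <- generateGenome(2, 1e5, siteDensity = 4, seed = 1)
#' chromSizes(gn)
#' @export
generateGenome <- function(nChroms, chromLength, siteDensity = 4,
                           seed = 1L, centromereFraction = 0.1,
                           telomereLength = 2e4) {
  .assertCount(nChroms, "nChroms", min = 1L)
  if (any(chromLength < 1e4))
    stop("'chromLength' must be >= 10 kb", call. = FALSE)
  if (siteDensity <= 0)
    stop("'siteDensity' must be positive", call. = FALSE)
  lens <- as.integer(rep_len(chromLength, nChroms))
  names(lens) <- paste0("chr", seq_len(nChroms))

  set.seed(as.integer(seed))
  sites <- lapply(lens, function(L) {
    n <- rpois(1L, siteDensity * L / 1000)
    sort(unique(as.integer(floor(runif(n, 0, L)))))
  })

  cen <- GenomicRanges::GRanges()
  tel <- GenomicRanges::GRanges()
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    half <- round(centromereFraction * L / 2)
    mid <- round(L / 2)
    cen <- .cGR(cen, .toGRanges(chrom, mid - half, mid + half))
    tl <- min(telomereLength, floor(L / 4))
    tel <- .cGR(tel, .toGRanges(chrom, c(0L, L - tl), c(tl, L)))
  }
  methods::new("HicGenome", chromSizes = lens, restrictionSites = sites,
               centromeres = cen, telomeres = tel)
}
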