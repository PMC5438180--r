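# rddmHiC

Calling long-range chromosomal interactions from Hi-C read pairs and
quantifying how RNA-directed DNA methylation (RdDM) targets, chromatin
states and gene expression relate to those interactions across
genotypes.

## The scientific problem

In *Arabidopsis*-like plant genomes, the RdDM pathway (Pol V/NRPE1,
AGO4) deposits CHH methylation at target loci and represses them. A
central question is whether RdDM also controls **3D genome
organization**: do RdDM targets engage in long-range chromosomal
interactions, and does losing RdDM (in *nrpe1* or *ago4* mutants)
release interactions between repressed genes and their distant
regulatory elements? Answering this requires an interaction caller that
works at restriction-fragment scale, permutation-based enrichment
statistics over genomic feature classes (differentially methylated
bins, chromatin states, promoters), and genotype contrasts with
replicate-level significance.

rddmHiC implements that workflow end-to-end for analysts working with
binned Hi-C contact data, plus a seeded synthetic-data generator that
plants known loop structure so every statistic can be validated
quantitatively without any sequencing download.

## The method in brief

* **Site filter.** An intra-chromosomal read pair is kept iff strictly
  more than 3 restriction sites separate its ends (removes
  self-ligation/adjacent-fragment artefacts); inter-chromosomal pairs
  are exempt.
* **Simple caller.** Pairs are binned at 250 bp
  (`bin = floor(pos / 250)`). The count threshold *t* is the smallest
  integer such that the fraction of bin pairs at the shortest admitted
  distance (4 bins) with count ≥ *t* is ≤ 5 %, floored at 2 reads; it is
  applied to all bin pairs at distance ≥ 4 bins and to inter-chromosomal
  bin pairs.
* **Interaction score.** For a call with read count *c* in a sample
  with *R* retained pairs and *L* called loops,
  `score = c · R / L`; score cutoffs 5 / 10 / 15 give nested call sets,
  with 10 as the high-confidence default.
* **Stringent caller.** 1 kb bins, ICE matrix balancing, expected
  counts per (merged, smoothed) distance stratum from the
  bias-corrected counts, upper-tail Poisson p-values for pairs > 3 kb
  apart, and a permutation FDR: the largest p cutoff such that random
  equal-size interaction sets from the tested universe contain ≤ 5 %
  of p-values at or below it.
* **Architecture.** Compartment eigenvector (first PC of the per-bin
  contact-correlation matrix, larger cluster positive), telomere
  metaplots in 20 kb offset bins, centromere–centromere fractions of
  inter-chromosomal calls.
* **Feature statistics.** Active/inactive chromatin from the KDE
  valley of log2(H3K4me2/H3K9me2); methylation high/low per context;
  differentially methylated bins (DMBs) via the mutant/wild-type CHH
  ratio (< 0.25 → DMB, > 0.75 → unchanged); observed/expected call
  enrichment against random draws from mappable non-centromeric bins;
  paired t-tests across replicates; promoter (1 kb upstream)
  interaction statistics, TSS×DMR interaction surfaces with
  random-background subtraction, gene–DMR connection ratios with a
  random-gene control, and AGO4 promoter/distal localization classes
  (distal = ≥ 3 restriction sites from the gene and its promoter).

## Worked example

```r
library(rddmHiC)

genome <- generateGenome(nChroms = 3, chromLength = 1e6,
                         siteDensity = 4, seed = 11)
tracks <- generateTracksAndFeatures(genome,
            list(nGenes = 150, nDmrs = 30, nOtherMeCHH = 30), seed = 12)
truth  <- buildTruth(genome, tracks, seed = 13)
truth
#> SyntheticTruth: 58 planted loops ( expression=40, rddm=18 ), 30 suppressed regions
#>   genotypes: Col0, nrpe1, ago4 (wild-type: Col0 )

gts <- genotypeNames(truth)
pairs <- lapply(setNames(nm = gts), function(g)
  combineReplicates(lapply(1:2, function(r)
    simulateReadPairs(genome, truth, g, 2e5, replicate = r,
                      seed = 100 * match(g, gts))), genome))
filtered <- lapply(pairs, filterPairsBySites, genome = genome)
binned   <- lapply(filtered, binPairs, resolution = 250,
                   byReplicate = TRUE)
calls <- lapply(setNames(nm = gts), function(g)
  scoreCalls(callSimple(binned[[g]], deriveCountThreshold(binned[[g]]),
                        sample = g),
             totalReads = nrow(filtered[[g]])))
calls$Col0
#> InteractionCalls (simple) for sample 'Col0': 933 calls at 250 bp

round(fitDecaySlope(decayCurve(filtered$Col0, resolution = 250)), 3)
#> [1] -0.975
```

The fitted log–log decay slope −0.975 recovers the generating exponent
(α = 1) of the contact decay law. Enrichment of high-confidence calls
at DMBs then shows the RdDM direction — wild-type depleted, mutants
enriched:

```r
ct  <- rddmHiC:::.trackTable(getTrack(tracks, "control_coverage"), 250)
cen <- rddmHiC:::.grToBins(centromeres(genome), 250)
universe <- ct[ct$score >= 1 &
  !paste(ct$chrom, ct$bin) %in% paste(cen$chrom, cen$bin),
  c("chrom", "bin")]
chh <- classifyMethylation(getTrack(tracks, "meCHH.Col0"), 0.1, 250)
dmb <- classifyDmbs(chh$level,
         rddmHiC:::.trackTable(getTrack(tracks, "meCHH.nrpe1"), 250)$score,
         chh$meth_class == "high")
dmbBins <- data.frame(chrom = chh$chrom, bin = chh$bin)[
  !is.na(dmb) & dmb == "nrpe1_DMB", ]
for (g in gts) {
  e <- overlapEnrichment(filterByScore(calls[[g]], 10), dmbBins,
                         universe, nPerm = 200, seed = 1)
  cat(sprintf("%-6s observed %3d  expected %6.1f  ratio %5.2f\n",
              g, e$observed, e$expected, e$ratio))
}
#> Col0   observed   2  expected   10.4  ratio  0.19
#> nrpe1  observed 235  expected   13.1  ratio 17.88
#> ago4   observed 232  expected   12.9  ratio 18.05
```

Wild-type calls at DMBs sit well below the random expectation
(observed 2 vs expected 10.4, ratio 0.19) while both RdDM mutants gain
interactions at the same bins (ratios ≈ 18) — the planted suppression
is recovered in the correct direction. `runPipeline(config, outdir)`
runs all stages from a YAML config and writes a hashed reproducibility
manifest; `pipelineReport(outdir)` condenses a run into one table.

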