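---
title: "Calling chromosomal interactions and quantifying RdDM-dependent looping: methods and design"
author: "rddmHiC package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

rddmHiC implements a complete desk-scale pipeline for studying how
RNA-directed DNA methylation (RdDM) relates to long-range chromosomal
interactions in a plant genome: interaction calling from Hi-C read
pairs, genome-architecture summaries, permutation-based feature
enrichment, and promoter-centred gene statistics, together with a
seeded synthetic-data generator that plants known structure so every
stage can be tested quantitatively without sequencing data. The
package consumes aligned read pairs (or simulates them); read
alignment, differential-expression model fitting and peak calling are
out of scope — DE labels, peaks and tracks are inputs.

# The two interaction callers

**Simple (loose) caller.** Read pairs are first filtered on the
restriction map: an intra-chromosomal pair is kept only when strictly
more than `minSites` (default 3) cut sites of the 4-base-cutter lie
between its two ends, which removes self-ligation and
adjacent-fragment artefacts; the rule is distance-based and therefore
not applied to inter-chromosomal pairs. Retained pairs are assigned to
250 bp bins by floor division of the 5' mapped position (0-based,
half-open bins). The read-count threshold is derived from the shortest
admissible distance: among all bin pairs exactly 4 bins apart, the
smallest integer *t* such that the fraction of those pairs with count
≥ *t* is at most 5% — ties therefore never exceed the nominal
fraction — floored at 2 reads so that every call is supported by two
independent ligation events. That count is then required of every bin
pair at distance ≥ 4 bins, and of inter-chromosomal bin pairs. Whether
the distance-4 pairs themselves are kept as calls is a flag
(`includeDerivationDistance`, default `TRUE`).

**Interaction score.** Each call's score is its read count multiplied
by the ratio of the sample's total retained read pairs to the total
number of loops called in that sample. "Total reads" means retained
pairs after the site filter — the raw sequenced total does not exist
for simulated data and would differ from the retained total only by a
sample-independent factor. Scores are monotone in count within a
sample, so the score cutoffs used throughout (5, 10, 15) give nested
call sets; 10 is the default "high confidence" cutoff and 15 is used
where noisy external signal (ChIP) must be compensated.

**Stringent caller.** Pairs are binned at 1 kb and each chromosome's
contact matrix is balanced by iterative correction (ICE): rows and
columns are repeatedly divided by their relative marginals until all
unmasked row sums agree to a relative tolerance; the input factorizes
exactly into the balanced matrix and the outer product of the returned
biases. The expected count of a bin pair more than 3 kb apart is
estimated from the ICE-normalized counts pooled per distance stratum
(strata with fewer than 50 occupied bin pairs are merged with
neighbours, then smoothed across adjacent strata in log space) and
scaled back by the pair's biases; significance is an upper-tail
Poisson test. This distance-stratified construction deliberately
replaces a spline fit of expected counts: it is simpler, monotone by
construction at desk scale, and is validated by null calibration and
planted-loop recovery rather than output identity with any external
tool. The permutation FDR then finds the largest p-value cutoff such
that, averaged over many random interaction sets of the same size
drawn from the tested universe, at most 5% of the random p-values fall
at or below it — calls must be unlikely to appear in random sets.

# Architecture summaries

The compartment eigenvector is computed directly as stated procedure:
correlation matrix of per-bin contact profiles, principal component
analysis, first component, with the larger cluster given the positive
sign. The telomere metaplot aligns all chromosome ends and averages
inter-chromosomal call ends per 20 kb offset bin; centromere
association is the fraction of inter-chromosomal calls with both ends
inside the centromere/pericentromere mask, per replicate and pooled.
The pericentromere extent is a configurable flank because no fixed
size is canonical.

# Classification and enrichment

Active/inactive chromatin is split at the valley of a kernel density
estimate of log2(H3K4me2/H3K9me2) between its two largest modes, with
a fallback split at 0 (and a warning) when the distribution is
unimodal. Methylation high/low thresholds default to 0.8/0.4/0.1 for
CG/CHG/CHH — these are implementation defaults chosen at the
antimodes typical of plant methylomes, since no printed values exist.
Differentially methylated bins (DMBs) are bins with high wild-type CHH
methylation whose mutant/wild-type ratio falls below 0.25; bins with
ratio above 0.75 are "other meCHH"; both boundaries exclusive, so a
ratio exactly at 0.25 or 0.75 is "neither". Features enter enrichment
only if they overlap at least one read of the decrosslinked-control
coverage track (Hi-C mappability).

Overlap enrichment counts calls with at least one end in a feature bin
(a call with both ends in features counts once) and divides by the
mean of the same statistic over seeded random draws of equal-size bin
sets from the mappable, non-centromeric universe (default 1000
permutations; the permutation count is an implementation default).
Per-replicate ratios use each replicate's own observed and expected
counts, making them depth-independent; replicate-level contrasts use
a standard two-sided paired t-test, with degenerate inputs (identical
vectors; zero-variance nonzero differences) reported explicitly
rather than as NaN.

# Gene-centred statistics

Putative promoters are 1 kb upstream of the TSS, strand-aware and
clipped at chromosome edges. Expression groups are the 5% of genes
with the lowest/highest RPKM (and a 5% band centred at the median
rank), ranked with gene-id tie-breaking for determinism. The
TSS x DMR surface filters calls below 10 kb separation, accumulates
the **sum** of call scores into cells indexed by (offset from TSS,
offset from DMR centre) in 250 bp steps over a ±5 kb window (the
window size is an implementation default; planted and observed peaks
lie within 1–2 kb of the TSS), subtracts the mean surface of
size-matched random region sets, and also returns a min–max scaled
copy. Summation rather than per-cell averaging makes the surface
reflect total planted signal; with averaging, one isolated
high-scoring background call can outweigh a genuine peak supported by
many calls. Distal regulatory regions for AGO4 localization are call
ends at least three restriction sites away from the gene body plus its
promoter; rank-sum tests use the exact distribution below 20 per
group and the tie-corrected normal approximation otherwise.

# The synthetic-data generator

The generator is the package's study fixture and defines its
conditions: five chromosomes of 2 Mb, restriction sites as a seeded
Poisson process at 4 sites/kb (a 4-cutter lands about every 256 bp), a
central centromere mask (10% of the chromosome) and 20 kb telomere
masks, three genotypes (wild-type plus two RdDM mutants) with three
replicates each, and on the order of a million read pairs per
replicate.
Background intra-chromosomal distances follow a truncated shifted
power law p(d) ∝ (d + d0)^(−α) with α = 1 and d0 = 1 kb (the offset
avoids the singularity at zero); a configurable fraction of pairs is
inter-chromosomal, optionally clustered at a handful of focal points
inside telomere/centromere masks — real centromere and telomere
association is punctate, and uniform spreading would never recur in
the same 250 bp bin pair at desk-scale depth. Replicates derive their
seeds by base seed + replicate index.

Planted structure has two layers. *Expression loops* join the
promoters of the most highly expressed genes to TF peaks with equal
intensity in all genotypes, coupling promoter contacts to expression.
*RdDM loops* join promoters of mutant-up-regulated genes to DMRs (and
remaining DMRs to random distal sites) with multiplier 1 in the
mutants and 0 in wild-type, and additionally the wild-type background
at DMR regions is thinned to 50% retention. Both choices encode the
model under test — RdDM prevents chromosomal interactions at its
targets in wild-type — and were fixed by arithmetic on expected call
counts so that wild-type DMB enrichment sits below 1 while mutants
gain both enrichment and gene–DMR connections. A variant in which a
minority of RdDM loops keeps a weak wild-type intensity is available
(`wtRddmFraction`) but defaults to off: even a handful of wild-type
loop calls at DMBs overwhelms the small expected overlap count at
desk-scale call density and would invert the wild-type depletion.
Methylation tracks plant the classification structure the analyses
need (mutant/wild-type CHH ratio < 0.25 at DMRs, > 0.75 at other
high-CHH regions) and chromatin tracks draw log-ratios from two
Gaussian modes ±2 with SD 0.5.

What the generator does **not** emulate: sequence-level reads,
ligation-junction chimeras, PCR duplicates (an optional duplication
rate exists but defaults to 0 because no duplicate handling is
described for the original protocol), crosslinking-strength effects,
and the fine structure of real methylomes beyond the planted
classes. Passing tests therefore demonstrate that the statistics
measure planted structure correctly at realistic depth — not that the
pipeline would be robust to artefacts absent from the simulation.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in the pairs
  format; BED files on disk follow BED conventions; `GRanges` objects
  are 1-based internally as usual for that container.
* Threshold boundaries: count threshold "smallest integer with tail
  fraction ≤ 5%"; methylation high is `level ≥ threshold`; DMB ratio
  boundaries are strict inequalities; MNase "reduced" is ratio
  strictly > 2; TF binding is fold change ≥ 4; distal is ≥ 3 sites.
* ICE masks zero-mass rows and errors (reporting the residual) if it
  fails to converge; an all-zero matrix is an error.
* The permutation FDR restricts candidate cutoffs to below four times
  the alpha-quantile of the universe p-values — the cutoff cannot
  exceed roughly the alpha-quantile, so larger candidates need not be
  Monte-Carlo checked.
* Degenerate inputs favour explicit results over NaN: identical
  replicate vectors give p = 1; an all-equal p-value set yields a
  conservative cutoff below the minimum with a warning; a wild-type
  connection count of zero flags the ratio as undefined instead of
  dividing by zero.

# Problem sizes

The bundled tests exercise the pipeline on a 3 x 1 Mb genome with two
replicates of 1e5 pairs per genotype; the acceptance suite and
`scripts/acceptance.R` use the full study fixture (5 x 2 Mb, three
replicates of 1e6 pairs per genotype, three simulation seeds for
stochastic checks) and 1e6-pair simulations for decay-exponent
recovery. These sizes give every direction statistic comfortable
power while keeping a complete run on a single CPU within minutes.

# Interfaces

All functionality is exposed as documented R functions over S4 classes
(`HicGenome`, `SyntheticTruth`, `TrackBundle`, `BinnedContacts`,
`InteractionCalls`); `runPipeline(config)` orchestrates the stages
end-to-end from a YAML config with mandatory explicit seeds and writes
an MD5-hashed reproducibility manifest, and `pipelineReport(outdir)`
condenses a run into one summary table. For an analysis package of
this kind the function surface plus the pipeline driver are the
interface; no shell entry point is shipped.

# Known limitations

The stringent caller's distance-stratified expectation is coarser than
a spline fit near the minimum distance; inter-chromosomal significance
is not tested (the simple caller retains inter calls, the stringent
caller is intra-only by construction); the random-gene control for
gene–DMR connections is count-limited at desk scale, so its ratio is
reported but fluctuates when wild-type counts are near zero — the same
small-numbers caveat applies to shallow real data.
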