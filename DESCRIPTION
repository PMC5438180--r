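Package: rddmHiC
Title: Chromosomal Interaction Calling and RdDM Target Enrichment from Hi-C
        Read Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Calls long-range chromosomal interactions from Hi-C read pairs
        using restriction-site distance filtering and read-count thresholds,
        and quantifies how RNA-directed DNA methylation (RdDM) targets,
        chromatin states and gene expression relate to those interactions
        across genotypes. Provides a simple distance/count interaction
        caller with interaction scores, a stringent ICE-normalized
        distance-stratified caller with permutation-based FDR control,
        compartment eigenvector and telomere/centromere architecture
        summaries, permutation-based feature overlap enrichment, and
        promoter-centred gene looping statistics. A seeded synthetic-data
        generator produces genomes, restriction maps, chromatin and
        methylation tracks, expression tables and genotype-specific read
        pairs with planted loops, so the whole pipeline is testable without
        sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, data.table, GenomicRanges, IRanges,
        S4Vectors, GenomeInfoDb, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 'utils.R' 'AllClasses.R' 'synthetic-genome.R' 'synthetic-tracks.R'
        'synthetic-truth.R' 'synthetic-pairs.R' 'fixture-io.R' 'hic-core.R'
        'caller-simple.R' 'caller-stringent.R' 'architecture.R'
        'enrichment.R' 'gene-looping.R' 'pipeline.R'
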