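Package: orchardQC
Title: Gene-Model Curation and Comparative QC for Haplotype-Resolved Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for the bespoke post-assembly stages of a
    haplotype-resolved plant genome project: rule-based gene-model curation
    (repeat-overlap, same-strand overlap and disjoint-isoform filters),
    evidence-tier gene subsetting, standardized gene nomenclature,
    orthogroup gene-count QC (z-score matrices, clustering order, UpSet
    counts), canonical k-mer haplome binning with reference-guided
    chromosome renaming and orientation, telomere tandem-repeat scanning,
    assembly statistics, plastome quadripartite-structure detection, and a
    seeded synthetic-data generator with machine-readable planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'annotation-io.R'
    'curation.R'
    'evidence.R'
    'nomenclature.R'
    'orthostats.R'
    'haplobin.R'
    'seqstats.R'
    'organelle.R'
    'simulate.R'
    'pipeline.R'
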