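Package: PloidyScan
Title: Ploidy-Aware Genome Scans for Repeated Substrate Adaptation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genome-scan toolkit for mixed-ploidy (diploid and
    autotetraploid) population resequencing data. Provides ploidy-aware
    diversity and differentiation estimators (nucleotide diversity, Tajima's D,
    Weir-Cockerham F_ST and the Rho statistic, which excludes the
    within-individual variance stratum so values are comparable across ploidy
    levels), windowed outlier scans replicated over population pairs, an
    order-statistics test of repeated adaptation across lineages, a
    latent-factor-corrected genotype-environment association scan against a
    soil-chemistry gradient, selective-sweep magnitude and breadth profiling,
    fixation and adaptation-mode comparisons between ploidies, and a
    protein-interaction degree permutation test. Includes a fully synthetic
    mixed-ploidy study generator with planted sweeps so the entire pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
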