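Package: MantelQTL
Title: Distance-Based Multi-Locus QTL Mapping with Mantel Correlations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-locus genotype-phenotype association mapping for
    genetically heterogeneous populations via distance matrix correlation.
    Pairwise Manhattan (or identity-by-state) distances between individuals
    are computed from SNP dosages and from composite phenotype categories,
    correlated with the Mantel procedure, and marker sets are grown by
    forward selection with two overfitting guards: a per-marker permutation
    p-value gate and a label-shuffled empirical null that converts cumulative
    correlation curves to Z-scores. Marker sets detected under different
    environmental conditions are compared by Fisher exact overlap tests, and
    genes near reproducible markers are tested for gene-set
    overrepresentation. Includes a simulator of heterogeneous-stock-like
    founder mosaic genomes and correlated, condition-dependent phenotypes
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, QTL, Regression, GeneSetEnrichment
RoxygenNote: 7.3.3
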