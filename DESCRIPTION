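Package: twinclock
Title: Lineage Tracing and Bayesian Timing of Twin-Shared Somatic Clones
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the shared clonal origin of a somatic clone
    observed in both members of a twin pair and times their most recent
    common ancestor (MRCA). Provides a consensus somatic call-set builder
    over multiple variant callers, conversion of variant allele
    frequencies to cancer cell fractions with purity and copy-number
    adjustment, Dirichlet-process binomial mixture clustering of cancer
    cell fractions in one or two dimensions, pigeonhole assignment of
    clusters to cell lineages, clock-like N[C>T]pG mutation counting
    from reference context, and a Bayesian Poisson model for the MRCA
    time fitted by Markov chain Monte Carlo, validated against a
    deterministic quadrature oracle and scored by bridge-sampling
    marginal likelihoods. A synthetic twin-lineage generator with full
    ground truth makes every stage testable without access to protected
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: SomaticMutation, VariantDetection, Bayesian, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
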