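Package: scpopsim
Title: Population-Scale Single-Cell RNA-Seq Simulation with Ground-Truth
    Genetic Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates population-scale single-cell RNA-seq counts with
    known ground truth using a gamma-Poisson hierarchical model. Gene
    means are sampled per individual from population-level gamma fits
    with a binned mean-variance trend, optionally quantile normalized to
    a single-cell gamma target, and perturbed by genetic (eQTL),
    cell-group, condition and batch effects before Poisson count
    sampling with biological-coefficient-of-variation inflation.
    Includes estimation of all model parameters from reference
    expression matrices and eQTL summary statistics, genotype ingestion
    and simulation, and an evaluation suite (pseudobulk Wilcoxon
    differential expression, simplified cis-eQTL mapping, confusion
    summaries, variance explained, silhouette widths) for benchmarking
    downstream analysis methods against the simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    edgeR,
    fitdistrplus,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
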