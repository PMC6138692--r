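Package: geostrat
Title: Geographically Structured Rare-Variant Association Pipelines
Version: 0.1.0
Authors@R: person("geostrat", "maintainers", email = "maintainers@geostrat.dev",
    role = c("aut", "cre"))
Description: Simulation and analysis of case-control whole-genome sequencing
    studies with fine-scale population structure. Generates spatially
    structured synthetic cohorts (geographically clustered rare variants,
    common-variant allele-frequency clines, distance-dependent IBD sharing,
    and externally sequenced controls with platform-specific genotype
    error) and implements the full analytic pipeline: genotype VCF I/O,
    sample- and variant-level quality control with an exact Hardy-Weinberg
    test, genetic relationship matrices, principal components and
    leave-one-out birthplace prediction, additive logistic score tests with
    genomic inflation assessment, genic burden tests (T1, T5,
    Madsen-Browning, Variable Threshold, SKAT), family-wise error
    calibration by phenotype simulation, and site-level cohort merging with
    differentiated-SNP filtering.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
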