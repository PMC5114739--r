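Package: immunedecomp
Title: Gene Expression Decomposition of the Tumor Immune Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rank-based decomposition of bulk tumor expression profiles into
    immune cell infiltration levels. Implements single-sample gene set
    enrichment (ssGSEA) scoring of immune cell signature collections,
    aggregate T cell and overall immune infiltration indices (TIS, IIS) and
    an antigen presenting machinery (APM) score, an in silico cell-mixture
    simulation and recovery benchmark with size-matched random-signature
    bootstrap nulls, a DNA methylation (beta value) leukocyte fraction
    estimator, and three-class immune infiltration clustering of tumor
    cohorts. Synthetic data generators for reference expression profiles,
    known-proportion mixtures, planted-class cohorts, and beta-value mixtures
    drive the validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, GeneSetEnrichment, ImmunoOncology, Transcriptomics
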