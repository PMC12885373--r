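Package: pcrbias
Title: PCR Amplification Bias in Microbiome Diversity Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how per-cycle PCR amplification bias distorts
    alpha- and beta-diversity analyses of amplicon sequencing data.
    Simulates read counts under a multinomial logistic-normal model with
    exponential per-taxon amplification efficiencies, fits the model by a
    collapse-Laplace-uncollapse strategy to recover unbiased compositions
    and per-cycle bias from calibration designs, propagates posterior
    uncertainty into bias estimands for Shannon, Simpson, Gini, Aitchison,
    Bray-Curtis and weighted UniFrac metrics, classifies estimands by
    perturbation invariance, maps composition-dependent bias over the
    three-part simplex, and searches for worst-case group comparisons via
    ANOVA/PERMANOVA delta-R-squared optimization.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq
Config/testthat/edition: 3
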