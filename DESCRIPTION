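Package: mixwas
Title: Phenotype Subtype Discovery and Genetic Heterogeneity Testing
Version: 0.1.0
Authors@R:
    person("Mixwas", "Developers", email = "mixwas@example.org", role = c("aut", "cre"))
Description: Two-step analysis of phenotypic subtypes in multi-trait cohorts.
    Step one learns latent subtypes with a covariate-aware multi-trait finite
    mixture of regressions (MFMR) fit by Expectation Conditional-Maximization,
    handling quantitative traits with Gaussian likelihoods and binary traits
    with probit links. Step two validates subtypes with SNP-by-subtype and
    covariate-by-subtype fixed-effect interaction tests (homogeneity,
    heterogeneity and global modes), genome-wide interaction scans with
    genomic-control diagnostics, and a polygenic variance-component test that
    partitions heritability into homogeneous and subtype-specific parts via an
    IID gene-environment mixed model fit by AI-REML. Includes comparator
    subtype estimators (Gaussian mixtures, canonical correlation and principal
    component scores), multivariate-normal and low-rank imputation for missing
    phenotypes, a full synthetic cohort simulator (Balding-Nichols population
    structure, gene-environment correlation, ascertainment, non-Gaussian noise
    and non-linear effect scenarios), and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
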