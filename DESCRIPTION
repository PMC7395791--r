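Package: pgsra
Title: Relative Accuracy of Polygenic Scores Across Ancestries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic prediction of the relative accuracy (RA) of
    polygenic scores transferred between ancestry-divergent populations,
    from reference-panel linkage disequilibrium and allele frequencies
    plus discovery GWAS summary statistics. Provides the closed-form RA
    predictor with known causal variants, a heuristic predictor based on
    candidate causal variants (LD r-squared > 0.45 within 100 kb of each
    genome-wide significant SNP), and a naive predictor that treats the
    significant SNPs themselves as causal, each with a multiplicative
    decomposition into effect-correlation/heritability, LD+MAF, and
    PGS-variance terms. Includes a two-population genotype simulator
    (Balding-Nichols drift with population-specific LD), a selection-aware
    causal effect model, linear-regression GWAS, PLINK-style LD clumping,
    PGS scoring, observed- and liability-scale R-squared, Hudson F_ST, and
    replicate experiment orchestration for validating predicted against
    observed RA on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
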