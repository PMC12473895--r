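Package: phenogp
Title: Genomic and Phenomic Prediction for Factorial Hybrid Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Multi-kernel genomic (GP), phenomic (PP), and combined (GP+PP)
    prediction for hybrids from factorial (NC-II) mating designs evaluated in
    multi-environment trials. Builds VanRaden genomic relationship matrices
    for female and male parents, Kronecker-product specific-combining-ability
    kernels, near-infrared (NIR) spectral relationship matrices from
    Savitzky-Golay first-derivative pretreated reflectance, and Hadamard
    genotype-by-environment interaction kernels. Variance components,
    likelihood-ratio tests, and broad- and narrow-sense heritabilities are
    estimated by REML; predictions come from a multi-kernel Bayesian RKHS
    Gibbs sampler evaluated under CV1/CV2/CV3 cross-validation schemes with
    Tukey model comparison. A synthetic-data module simulates factorial
    trials (parent genotypes, plot-level traits, smooth NIR spectra) with
    known variance structure so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    multcomp,
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
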