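Package: museomics
Title: Museum-Genomics Consensus Reconstruction, Relaxed-Clock Dating, and
    Meristic Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative species-delimitation toolkit for museum genomics.
    Simulates degraded historical sequencing libraries (short fragments,
    terminal cytosine-deamination damage, low endogenous content), maps reads
    with a seed-and-extend k-mer mapper with mismatch-budget stringencies,
    reconstructs mitochondrial consensus sequences by iterative majority-rule
    reference refinement, estimates node ages on a fixed topology with a
    partitioned GTR+Gamma(+I) likelihood, an uncorrelated lognormal relaxed
    clock, a Yule tree prior and normal node calibrations via
    Metropolis-Hastings MCMC, and analyses meristic scale-count data with
    chi-squared, Fisher exact, two-way ANOVA/ANCOVA and standardised PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
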