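Package: gblupd
Title: Genomic Evaluation of Dairy Cattle with Additive and Dominance Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Genomic best linear unbiased prediction (GBLUP) for repeated-record
    dairy traits with additive and dominance genetic effects. Builds additive (G)
    and dominance (D) genomic relationship matrices from SNP allele counts,
    estimates variance components by restricted maximum likelihood (EM warm-up
    plus average-information updates), solves for breeding values, dominance
    deviations and total genetic values including unphenotyped animals, compares
    the additive and additive-plus-dominance models with a boundary-corrected
    mixture chi-square likelihood-ratio test, computes genomic inbreeding measures
    and their correlation with dominance deviations, and assesses predictive
    ability by fivefold cross-validation in which paternal half-sib families are
    confined to a single fold. Includes a seeded simulator of half-sib populations
    with known additive, dominance and permanent-environmental effects for
    parameter-recovery and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
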