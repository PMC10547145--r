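Package: pedgxe
Title: Variance-Components Analysis of Genotype-by-Environment
    Interaction in Extended Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood variance-components analysis of
    genotype-by-environment interaction (GxE) for continuous
    environmental indices in family data. Computes pedigree kinship
    matrices, fits the classical polygenic mixed model and reports
    heritability, genetically corrects heritable environment variables
    by best linear unbiased prediction (BLUP), fits a GxE model in
    which the additive genetic variance and the genetic correlation
    are exponential functions of the environment (covariance
    K (Hadamard) Psi + Delta), and performs the two-stage
    likelihood-ratio testing protocol with mixture chi-square
    reference distributions appropriate for boundary parameters.
    Includes a synthetic extended-pedigree data generator so the full
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
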