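Package: lipidremodel
Title: Leaf Lipidome Remodeling Analysis Under Heat Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing leaf lipidome remodeling in temperature-stress
    experiments on crop populations. Parses lipid shorthand nomenclature
    (headgroup classes, acyl chains, oxidized chains), applies quality-control
    filters based on limits of detection and quality-control-pool coefficients
    of variation, computes unsaturation indices and occurrence-weighted acyl
    chain fold-change matrices, performs two-factor randomized-complete-block
    treatment comparisons with least-squares means and Fisher's LSD, discovers
    multivariate structure (PCA, Spearman co-occurrence clustering, Ward
    genotype clustering with tolerance classification), summarizes SNP marker
    distributions against size-proportional expectations, and simulates
    synthetic lipidome data with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
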