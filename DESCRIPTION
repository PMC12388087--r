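Package: mrpath
Title: Two-Sample Mendelian Randomization with Mediation, Multivariable
    MR and Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for causal inference from GWAS summary statistics:
    reading and harmonizing per-SNP association records, selecting genetic
    instruments by significance, allele frequency, instrument strength and
    greedy LD clumping, estimating causal effects with Wald-ratio,
    inverse-variance-weighted and MR-Egger models together with Cochran's Q
    and Egger-intercept sensitivity statistics, decomposing effects through
    a mediator with two-step mediation MR and the product-of-coefficients
    proportion mediated, estimating joint direct effects with multivariable
    MR, and testing for a shared causal variant at a locus with
    approximate-Bayes-factor colocalization under the five-hypothesis
    posterior model. Includes a summary-statistics simulator with known
    exposure-mediator-outcome causal structure, LD blocks and pleiotropy
    for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
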