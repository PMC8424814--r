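Package: cpimpact
Title: Counterfactual Impact of Clinical Pharmacy Intervention Acceptance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to study what would happen to hospital outcomes if every
    clinical pharmacy intervention (CPI) were accepted by physicians instead of
    the usual ~80%. Consolidates per-intervention log records into per-admission
    accepted/rejected summary records via an ordinal scoring scheme, fits a
    generalized regression (Gaussian-kernel exemplar) network to predict
    post-intervention length of stay and other outcomes, and estimates the
    effect of full acceptance by counterfactual reassignment with paired
    nonparametric tests, permutation variable-impact ranking, group-comparison
    tables, and paired-difference sample-size calculators. Includes a
    configurable synthetic data generator emulating the structure of a
    hospital CPI registry with a known causal effect for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
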