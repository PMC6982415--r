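Package: medperm
Title: Residual-Permutation and Bootstrap Tests for the Mediated
    Indirect Effect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Permutation tests for the indirect effect in single-mediator
    regression models with covariate adjustment, aimed at studies with
    small sample sizes.  Implements two tests that permute residuals
    under the reduced (null) models in the style of Freedman and Lane --
    a direct test of the indirect effect (IERM) and a supremum test of
    the composite null hypothesis (PSRM) -- together with the standard
    full-model residual permutation test (IEFM) and percentile,
    bias-corrected, and bias-corrected accelerated bootstrap
    comparators.  Includes a correlation-structure data generator, a
    catalogue of simulation conditions, and a seeded simulation harness
    for estimating type I error and power with Wald-bound flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
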