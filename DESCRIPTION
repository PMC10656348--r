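Package: mmlpower
Title: Power Analysis for Wald, Likelihood-Ratio, Score, and Gradient Tests
    of Linear Hypotheses in Marginal Maximum Likelihood IRT Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and sampling-based power analysis for the Wald,
    likelihood-ratio, score, and gradient tests of arbitrary linear
    hypotheses on the item parameters of item response theory models
    estimated by marginal maximum likelihood (2PL and generalized partial
    credit families, including two-group differential item functioning
    layouts). Noncentrality parameters are obtained either analytically,
    by evaluating the expected test statistics over the full response
    pattern space with Gauss-Hermite quadrature over the latent trait, or
    by a large-sample sampling approximation. Power curves and required
    sample sizes follow from noncentral chi-square distributions. Includes
    marginal maximum likelihood fitting of restricted and unrestricted
    models, the observed test statistics, and synthetic response
    generators for simulation-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    pracma,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
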