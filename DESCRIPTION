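Package: irtalign
Title: Alignment Estimation of Factor Means and Variances for
    Multiple-Group Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing latent factor means and variances across
    many groups measured with binary items, without requiring exact
    measurement invariance.  Fits the multiple-group two-parameter
    logistic (or probit) item response model by marginal maximum
    likelihood with Gauss-Hermite quadrature, tests configural, metric
    and scalar invariance by likelihood-ratio chi-square, and implements
    the alignment method: group factor means and variances are chosen to
    minimise a component-loss simplicity function over all pairwise
    differences of aligned item parameters, preserving the configural
    likelihood.  Post-alignment tools flag significantly non-invariant
    item parameters per group, summarise non-invariance rates against the
    25 percent rule of thumb, rank groups by factor mean with pairwise
    significance tests, and assess alignment quality by Monte Carlo
    simulation (correlation between generating and estimated factor
    means).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
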