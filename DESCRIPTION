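Package: derangetropy
Title: Information-Density Transforms of Probability Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes the derangetropy functional, a closed-form transform
    that maps a probability density f with distribution function F to a new
    density proportional to sin(pi*F(x)) F(x)^F(x) (1-F(x))^(1-F(x)) f(x),
    describing how informational content is spread over the support of f.
    Provides the analytic distribution families used in its study (uniform,
    normal, exponential, Wigner semicircle, arcsine) plus kernel-based
    empirical estimation from raw samples; the decomposition of the
    log-density into modulation and structural informational energies with
    equilibrium analysis; verification of the governing second-order ODE
    (residuals, integrating factor, recovered coefficients, initial slope);
    recursive self-application of the functional with convergence
    diagnostics toward a point mass at the median; and a per-channel
    pipeline for multichannel signal amplitude distributions with a
    synthetic signal generator.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
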