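Package: rsmkin
Title: Response Surface Optimization and First-Order Kinetics for
    Pesticide Biodegradation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for optimizing microbial pesticide-degradation
    experiments. Builds five-level central composite designs with real/coded
    factor conversion, fits the second-order (quadratic) response-surface
    polynomial by ordinary least squares with a full ANOVA, PRESS-based
    predicted R-squared, leverage/studentized-residual/Cook's distance
    diagnostics, compact-letter mean grouping, stationary-point (canonical)
    analysis, constrained optimum search and Box-Cox transformation scans.
    Also fits first-order dissipation kinetics C(t) = C0*exp(-k*t) with
    half-life t1/2 = ln(2)/k and treatment-versus-control comparisons, and
    ships a replicate-aware synthetic-data generator plus a bundled
    allethrin-biodegradation design table for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
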