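Package: guidedev
Title: Accuracy Analysis for Static Computer-Assisted Implant Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the positional accuracy of static
    computer-assisted implant surgery (sCAIS). Implements point-based rigid
    registration of digital dental casts to CBCT space (Kabsch/SVD best fit,
    for dental-surface landmarks or fiducial markers), the standard
    planned-versus-placed implant deviation metrics (global, lateral and depth
    deviation at platform and apex, and angular deviation), fiducial- and
    target-registration-error diagnostics, a seeded synthetic cohort generator
    emulating anisotropic metal-artifact registration noise and guide
    mechanical error, and the accompanying statistics layer (descriptive
    summaries, pooled and Welch two-sample t tests from raw data or summary
    statistics, one-way ANOVA with Tukey-Kramer multiple comparisons,
    unbalanced Type III factorial ANOVA, weighted marginal means, and
    two-group sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
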