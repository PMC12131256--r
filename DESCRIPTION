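Package: flexrig
Title: Four-Point Bending Mechanics and Group Comparison of Plant Tool Materials
Version: 0.1.0
Authors@R:
    person("flexrig", "maintainers", email = "flexrig@example.org", role = c("aut", "cre"))
Description: Measurement-to-inference pipeline for the biomechanics of plant
    materials used as flexible probing tools. Reads raw four-point-bending
    force-displacement traces, extracts the initial slope, computes flexural
    rigidity (EI) via Euler-Bernoulli beam theory, derives the elastic modulus
    (E) from regular cross-sections, applies quality-control filtering, groups
    samples by tool-selection categories, and compares groups with linear mixed
    models (per-plant random intercept, type-II F tests with Satterthwaite
    denominator degrees of freedom, Tukey-adjusted estimated-marginal-mean
    contrasts). Includes a hierarchical synthetic-study generator with known
    ground truth so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
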