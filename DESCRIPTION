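Package: vavr
Title: Virtual Aortic Valve Replacement Hemodynamics
Version: 0.1.0
Authors@R: person("VAVR", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for virtual therapy planning of surgical aortic valve
    replacement. Computes quantitative flow-profile metrics (normalized flow
    displacement, wall parallelism, flow angle, peak velocity) on
    cross-sectional velocity fields, predicts transvalvular pressure
    gradients across prosthesis sizes at rest and under simulated physical
    stress with a reduced-order (simplified Bernoulli) model, grades
    stenosis severity and patient-prosthesis mismatch, and runs the
    rank-based cohort statistics (Wilcoxon signed-rank, Wilcoxon-Mann-Whitney,
    relative effects, Benjamini-Hochberg adjustment). Includes a synthetic
    4D-flow-like velocity-plane and cohort generator with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
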