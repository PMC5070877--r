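Package: tempomem
Title: Analysis of Absolute Tempo Memory Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying absolute memory for musical tempo with
    identification and production tasks on a logarithmic 'semitempo' scale.
    Builds the scale (equal steps of 2^(1/12) in beats per minute), estimates
    produced tempo from tap-onset trains, scores responses in semitempo units
    with a +/- 1 semitempo correctness band, compares participants against
    chance with binomial-tail thresholds backed by a permutation null and an
    analytic log-uniform range null, classifies participants into above-chance
    quadrants, analyses accuracy by serial position in the learning set
    (bow effect), summarises groups (percent correct, mean error, target versus
    response regression, split-plot ANOVA), and simulates synthetic cohorts
    from a generative noisy-memory model for calibration and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
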