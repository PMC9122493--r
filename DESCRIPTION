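Package: visgamma
Title: Simulation and Analysis of Color-Induced Visual Gamma Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying visually induced gamma-band oscillations to
    chromatic stimuli in source-level MEG signals. Implements DKL cone-contrast
    stimulus calibration from display emission spectra, a synthetic
    virtual-dipole trial generator with condition-level ground truth, a QUEST
    Bayesian adaptive staircase, multitaper baseline-normalized power-change
    spectra, a constrained three-candidate spectral peak model selected by
    adjusted R-squared, event-related field N70 feature extraction, and the
    accompanying statistical layer (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Holm-corrected pairwise tests, JZS Bayes
    factors, bootstrap confidence intervals, and t-max permutation-corrected
    correlation courses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
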