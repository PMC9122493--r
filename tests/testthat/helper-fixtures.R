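# Shared fixtures: small colorspace objects and an environment for results
# that several test files reuse (built lazily so each file stays standalone).

fix_env <- new.env(parent = emptyenv())

fixture_fundamentals <- function() {
  if (is.null(fix_env$fund)) fix_env$fund <- synthetic_cone_fundamentals()
  fix_env$fund
}

fixture_monitor <- function() {
  if (is.null(fix_env$mon))
    fix_env$mon <- synthetic_monitor(fixture_fundamentals())
  fix_env$mon
}

fixture_calibration <- function() {
  if (is.null(fix_env$cal)) {
    mon <- fixture_monitor()
    lms <- as.numeric(mon$K %*% mon$background_guns)
    fix_env$cal <- dkl_calibration(cone_excitation_values(lms[1], lms[2],
                                                          lms[3]))
  }
  fix_env$cal
}

# a neutral single-participant effect set
neutral_fx <- function(n_dipoles = 1, sign = 1)
  list(freq_offset = 0, freq2_offset = 0, gain = 1,
       dipole_signs = rep(sign, n_dipoles))

# quick trial-average change spectrum for a condition spec via the batched
# internal engine (single participant)
condition_change_spectrum <- function(spec, n_trials = 30, n_dipoles = 8,
                                      seed = 1, fx = neutral_fx(n_dipoles)) {
  cfg <- spectral_config()
  bl <- visgamma:::synth_condition_block(spec, fx, n_trials, seed, n_dipoles)
  res <- visgamma:::analyze_participant_blocks(
    stats::setNames(list(bl), spec$name), cfg)
  attr(res$fits[[1]], "change")
}
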