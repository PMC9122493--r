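# Synthetic virtual-dipole trial generator.
#
# Each trial is 1/f background noise over the full trial (-1.2 to +1.4 s
# around stimulus onset at 1200 Hz) plus, post-onset: a narrowband gamma
# sinusoid with per-trial random phase (induced, not phase-locked), an
# optional second high-gamma sinusoid with an independently drawn frequency,
# and a biphasic N70-like evoked deflection whose polarity follows the
# per-dipole random sign. Injected magnitudes are calibrated so the analysis
# pipeline recovers the registry's percent power change and N70 z amplitude
# in expectation.

trial_duration_s <- c(-1.2, 1.4)

#' N70 template waveform
#'
#' Difference-of-Gaussians biphasic deflection (widths 8 and 20 ms) with a
#' single minimum of -1 at the requested latency.
#'
#' @param t_s time axis in seconds relative to stimulus onset.
#' @param latency_ms latency of the minimum, ms.
#' @return numeric vector, one value per timepoint; min is -1 at the latency.
#' @export
n70_template <- function(t_s, latency_ms) {
  dt <- t_s - latency_ms / 1000
  # surround weight 0.35 keeps the deflection dominant over the positive
  # lobes inside the 55-95 ms polarity-flip window at all study latencies
  w <- -(exp(-dt^2 / (2 * 0.008^2)) - 0.35 * exp(-dt^2 / (2 * 0.020^2)))
  w / abs(min(w))
}

# filtered window-mean of the unit template around its minimum (the quantity
# the ERF pipeline actually measures); shape is latency-invariant
template_window_gain <- function(cfg = spectral_config()) {
  key <- sprintf("tplgain_%d", cfg$fs)
  if (!is.null(calib_cache[[key]])) return(calib_cache[[key]])
  t_s <- seq(-0.3, 0.4, by = 1 / cfg$fs)
  w <- gauss_lowpass(n70_template(t_s, 80), cfg$fs)[, 1]
  i <- which.min(w)
  win <- round(0.010 * cfg$fs)
  g <- mean(w[(i - win):(i + win)])
  calib_cache[[key]] <- g
  g
}

#' Per-participant generative effects
#'
#' Between-participant variability of the synthetic cohort: a gamma-frequency
#' offset (population SD 8 Hz, shared by all of a participant's conditions),
#' an independent offset for the second gamma peak (SD 5 Hz), a log-normal
#' power gain (sigma 0.3) applied to every injected percent change, and
#' per-dipole random polarity signs. Offsets are drawn as randomly permuted
#' Gaussian quantiles and gains are normalized to cohort mean 1, so even
#' small cohorts are centered on the population values.
#'
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param n_dipoles dipoles per participant.
#' @param freq_sd,freq2_sd,gain_sigma population spread parameters.
#' @return list of per-participant lists with elements `freq_offset`,
#'   `freq2_offset`, `gain`, `dipole_signs`.
#' @export
participant_effects <- function(n_participants, seed, n_dipoles = 1,
                                freq_sd = 8, freq2_sd = 5, gain_sigma = 0.3) {
  with_seed(sub_seed(seed, 1L), {
    qs <- function(sd) {
      z <- stats::qnorm((seq_len(n_participants) - 0.5) / n_participants) * sd
      sample(z)
    }
    off1 <- qs(freq_sd)
    off2 <- qs(freq2_sd)
    gain <- exp(qs(gain_sigma))
    gain <- gain / mean(gain)
    lapply(seq_len(n_participants), function(i)
      list(freq_offset = off1[i], freq2_offset = off2[i], gain = gain[i],
           dipole_signs = sample(c(-1, 1), n_dipoles, replace = TRUE)))
  })
}

# truncated Cauchy change-onset times (x0 = 1.65 s, FWHM = 0.2 s, [0.3, 2] s)
draw_change_times <- function(n) {
  lo <- stats::pcauchy(0.3, 1.65, 0.1)
  hi <- stats::pcauchy(2.0, 1.65, 0.1)
  stats::qcauchy(stats::runif(n, lo, hi), 1.65, 0.1)
}

# one participant-condition block: full trial matrix for all dipoles/trials
synth_condition_block <- function(spec, part_fx, n_trials, seed,
                                  n_dipoles = 1, exponent = 1,
                                  noise_scale = 1, cfg = spectral_config()) {
  fs <- cfg$fs
  len <- round((trial_duration_s[2] - trial_duration_s[1]) * fs)
  t_ax <- (0:(len - 1)) / fs + trial_duration_s[1]
  f1 <- spec$gamma_freq_hz + part_fx$freq_offset
  f2 <- if (spec$second_peak_percent > 0)
    spec$second_peak_freq_hz + part_fx$freq2_offset else NA
  a1 <- calibrate_gamma_amplitude(f1, spec$gamma_percent * part_fx$gain,
                                  exponent, noise_scale, cfg = cfg)
  a2 <- if (!is.na(f2))
    calibrate_gamma_amplitude(f2, spec$second_peak_percent * part_fx$gain,
                              exponent, noise_scale, cfg = cfg) else 0
  # z-scoring divides each trial by its own baseline SD, so the noise scale
  # cancels from the measured z amplitude; calibrate at unit scale via the
  # mean reciprocal baseline SD, then rescale with the noise
  ref <- noise_reference(exponent, cfg)
  n70_amp <- noise_scale * abs(spec$n70_z) /
    (abs(template_window_gain(cfg)) * ref$mean_inv_sd)
  with_seed(seed, {
    change_t <- draw_change_times(n_trials)
    # per-trial random phases drawn as a randomly rotated, randomly permuted
    # balanced set: marginally uniform, but summing to zero across the
    # block's trials, so induced gamma cancels exactly in trial-averaged
    # ERFs (it is induced, not phase-locked) while per-trial power is that
    # of a fixed-amplitude sinusoid
    balanced_phases <- function()
      sample(2 * pi * (seq_len(n_trials) - 1) / n_trials +
               stats::runif(1, 0, 2 * pi)) %% (2 * pi)
    ph1 <- balanced_phases()
    ph2 <- balanced_phases()
    X <- noise_block(len, fs, exponent, n_trials * n_dipoles) * noise_scale
    post <- t_ax > 0
    tpl <- n70_amp * n70_template(t_ax, spec$n70_latency_ms) * post
    for (i in seq_len(n_trials)) {
      sig <- post * (a1 * sin(2 * pi * f1 * t_ax + ph1[i]) +
                       (if (a2 > 0) a2 * sin(2 * pi * f2 * t_ax + ph2[i]) else 0))
      cols <- (i - 1) * n_dipoles + seq_len(n_dipoles)
      X[, cols] <- X[, cols] + sig +
        outer(tpl, part_fx$dipole_signs[seq_len(n_dipoles)])
    }
    list(samples = X, n_trials = n_trials, n_dipoles = n_dipoles,
         change_time_s = change_t, condition = spec$name,
         dipole_signs = part_fx$dipole_signs[seq_len(n_dipoles)],
         fs = fs, onset_s = -trial_duration_s[1])
  })
}

block_trial <- function(block, i) {
  cols <- (i - 1) * block$n_dipoles + seq_len(block$n_dipoles)
  trial_timecourse(block$samples[, cols, drop = FALSE], fs = block$fs,
                   onset_s = block$onset_s, condition = block$condition,
                   dipole_signs = block$dipole_signs,
                   change_time_s = block$change_time_s[i])
}

#' Synthesize one trial
#'
#' Convenience wrapper around the block generator for a single trial.
#'
#' @param spec a [condition_spec()].
#' @param part_fx one participant's effects (see [participant_effects()]);
#'   defaults to a neutral participant with one positive dipole.
#' @param seed integer seed.
#' @param n_dipoles number of dipoles.
#' @param exponent,noise_scale background-noise parameters.
#' @param cfg a [spectral_config()].
#' @return a [trial_timecourse()].
#' @export
synthesize_trial <- function(spec, part_fx = NULL, seed = 1, n_dipoles = 1,
                             exponent = 1, noise_scale = 1,
                             cfg = spectral_config()) {
  part_fx <- part_fx %||% list(freq_offset = 0, freq2_offset = 0, gain = 1,
                               dipole_signs = rep(1, n_dipoles))
  block <- synth_condition_block(spec, part_fx, 1L, seed, n_dipoles,
                                 exponent, noise_scale, cfg)
  block_trial(block, 1L)
}

#' Generate a synthetic multi-participant dataset
#'
#' Every participant receives `n_trials` trials of every registry condition.
#' All randomness fans out from `seed` through per-(participant, condition)
#' sub-streams, so the dataset is byte-identical across runs and adding
#' participants leaves existing ones unchanged.
#'
#' @param registry a [condition_registry()].
#' @param n_participants number of participants (>= 1).
#' @param n_trials trials per participant and condition.
#' @param seed integer seed.
#' @param n_dipoles virtual dipoles per participant.
#' @param exponent,noise_scale background-noise parameters.
#' @param cfg a [spectral_config()].
#' @return an object of class `"synthetic_dataset"`: per-participant,
#'   per-condition sample blocks, trial metadata (`$trials`), participant
#'   effects, and the generating parameters.
#' @export
generate_dataset <- function(registry, n_participants, n_trials, seed,
                             n_dipoles = 1, exponent = 1, noise_scale = 1,
                             cfg = spectral_config()) {
  if (n_participants < 1) stopf("need at least one participant")
  fx <- participant_effects(n_participants, seed, n_dipoles)
  conds <- names(registry)
  blocks <- vector("list", n_participants)
  meta <- list()
  for (p in seq_len(n_participants)) {
    blocks[[p]] <- stats::setNames(vector("list", length(conds)), conds)
    for (ci in seq_along(conds)) {
      bl <- synth_condition_block(registry[[ci]], fx[[p]], n_trials,
                                  seed = sub_seed(seed, 2L, p, ci),
                                  n_dipoles, exponent, noise_scale, cfg)
      blocks[[p]][[ci]] <- bl
      meta[[length(meta) + 1L]] <- data.frame(
        participant = p, condition = conds[ci], trial = seq_len(n_trials),
        change_time_s = bl$change_time_s)
    }
  }
  structure(list(blocks = blocks, trials = do.call(rbind, meta),
                 participant_effects = fx, registry = registry,
                 n_participants = n_participants, n_trials = n_trials,
                 n_dipoles = n_dipoles, seed = seed, exponent = exponent,
                 noise_scale = noise_scale, cfg = cfg),
            class = "synthetic_dataset")
}

#' Extract one trial from a dataset
#'
#' @param dataset a [generate_dataset()] result.
#' @param participant participant index.
#' @param condition condition label.
#' @param trial trial index.
#' @return a [trial_timecourse()].
#' @export
dataset_trial <- function(dataset, participant, condition, trial) {
  bl <- dataset$blocks[[participant]][[condition]]
  tr <- block_trial(bl, trial)
  tr$participant <- participant
  tr
}

#' Weibull observer: probability correct and simulated response
#'
#' Two-alternative (left/right) observer with guess rate 0.5 and a Weibull
#' psychometric in contrast, parameterized by the contrast at which the
#' probability correct is 0.85.
#'
#' @param contrast presented change contrast in `[0, 1]`.
#' @param threshold_contrast contrast of 85% correct performance.
#' @param slope Weibull slope (beta).
#' @param lapse lapse rate (<= 0.02).
#' @param guess guess rate.
#' @return `weibull_correct_prob()` returns the probability of a correct
#'   response; `simulate_observer()` returns a logical draw.
#' @export
weibull_correct_prob <- function(contrast, threshold_contrast, slope = 3.5,
                                 lapse = 0.01, guess = 0.5) {
  if (any(contrast < 0 | contrast > 1)) stopf("contrast must lie in [0, 1]")
  f_req <- (0.85 - guess) / (1 - guess - lapse)
  a <- threshold_contrast / (-log(1 - f_req))^(1 / slope)
  guess + (1 - guess - lapse) * (1 - exp(-(contrast / a)^slope))
}

#' @rdname weibull_correct_prob
#' @param seed optional integer seed.
#' @export
simulate_observer <- function(contrast, threshold_contrast, slope = 3.5,
                              lapse = 0.01, seed = NULL) {
  p <- weibull_correct_prob(contrast, threshold_contrast, slope, lapse)
  draw <- function() stats::runif(length(p)) < p
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
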