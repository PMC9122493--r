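# Synthetic generator: noise spectrum, amplitude calibration against the
# spectral pipeline, observer psychometrics, and dataset structure.

test_that("background noise has the requested spectral slope", {
  # white limit: slope ~ 0
  fitslope <- function(exponent, n = 150) {
    X <- make_background_noise(2.6, exponent = exponent, seed = 31, n = n)
    ps <- 0
    for (j in seq_len(n)) ps <- ps + Mod(fft(X[, j]))[2:1560]^2 / n
    f <- (1:1558) * 1200 / 3120
    sel <- f >= 10 & f <= 100
    unname(coef(lm(log(ps[sel]) ~ log(f[sel])))[2])
  }
  expect_lt(abs(fitslope(0)), 0.1)
  expect_lt(abs(fitslope(1) + 1), 0.15)
  expect_lt(abs(fitslope(1.8) + 1.8), 0.15)

  expect_equal(colMeans(make_background_noise(1, seed = 1, n = 3)),
               rep(0, 3), tolerance = 0.05)
  expect_identical(make_background_noise(1, seed = 5, n = 2),
                   make_background_noise(1, seed = 5, n = 2))
  expect_error(make_background_noise(-1), "positive")
})

test_that("gamma amplitude calibration matches the pipeline's estimate", {
  cfg <- spectral_config()
  expect_equal(calibrate_gamma_amplitude(50, 0), 0)
  expect_error(calibrate_gamma_amplitude(50, -10), "non-negative")

  # doubling the target doubles power (amplitude^2)
  a50 <- calibrate_gamma_amplitude(46, 50)
  a100 <- calibrate_gamma_amplitude(46, 100)
  expect_equal(a100^2 / a50^2, 2, tolerance = 1e-9)

  # bin mode: Monte-Carlo over trials; the pipeline's change at the peak bin
  # matches the target within 10% relative
  amp <- calibrate_gamma_amplitude(46, 100, mode = "bin")
  t_ax <- (0:3119) / 1200 - 1.2
  set.seed(32)
  Ps <- 0; Pb <- 0; ntr <- 250
  X <- visgamma:::noise_block(3120, 1200, 1, ntr)
  for (i in seq_len(ntr)) {
    x <- X[, i] + amp * sin(2 * pi * 46 * t_ax + runif(1, 0, 2 * pi)) *
      (t_ax > 0)
    Ps <- Ps + visgamma:::mt_power_block(
      matrix(x[t_ax >= 0.3 - 1e-12 & t_ax < 1.3 - 1e-12]), cfg)[, 1] / ntr
    Pb <- Pb + visgamma:::mt_power_block(
      matrix(x[t_ax >= -1 - 1e-12 & t_ax < 0 - 1e-12]), cfg)[, 1] / ntr
  }
  chg <- 100 * (Ps - Pb) / Pb
  expect_equal(chg[47], 100, tolerance = 0.1)   # bin 46 Hz, 10% relative

  # band mode feeds the full loop: checked end-to-end in the acceptance
  # suite; here band calibration must require a larger amplitude than bin
  expect_gt(calibrate_gamma_amplitude(46, 50, mode = "band"),
            calibrate_gamma_amplitude(46, 50, mode = "bin"))
})

test_that("a null condition is indistinguishable from pure noise", {
  null_spec <- condition_spec("null", gamma_percent = 0, gamma_freq_hz = 46,
                              n70_z = 0)
  set.seed(33)
  n <- 40
  cfg <- spectral_config()
  bands <- matrix(NA_real_, n, 2)
  for (i in 1:n) {
    tr <- synthesize_trial(null_spec, seed = 4000 + i)
    ps <- epoch_power_spectrum(segment_epochs(tr, "stimulus", "high", cfg), cfg)
    x0 <- make_background_noise(2.6, seed = 8000 + i)[, 1]
    tr0 <- trial_timecourse(x0, onset_s = 1.2)
    ps0 <- epoch_power_spectrum(segment_epochs(tr0, "stimulus", "high", cfg), cfg)
    sel <- ps$freqs_hz >= 30 & ps$freqs_hz <= 110
    bands[i, ] <- c(mean(ps$power[sel]), mean(ps0$power[sel]))
  }
  expect_gt(t.test(bands[, 1], bands[, 2])$p.value, 0.01)
})

test_that("the fitted peak recovers the injected frequency", {
  reg <- condition_registry()
  chg <- condition_change_spectrum(reg$grating, n_trials = 40, n_dipoles = 12,
                                   seed = 35)
  fit <- peak_fit(chg)
  expect_lt(abs(peak_frequency(fit, "low") - reg$grating$gamma_freq_hz), 1.5)
})

test_that("observer psychometrics hit the 85% design point", {
  # P(correct) at very high contrast approaches 1 - lapse
  expect_gte(weibull_correct_prob(1, 0.2), 0.97)
  # guessing floor at zero contrast
  expect_equal(weibull_correct_prob(0, 0.5), 0.5)
  # the threshold parameter is the 85% point: Monte-Carlo vs closed form
  draws <- simulate_observer(rep(0.4, 10000), 0.4, seed = 36)
  expect_equal(mean(draws), 0.85, tolerance = 0.01)
})

test_that("datasets are reproducible with the documented structure", {
  reg <- condition_registry()
  ds1 <- generate_dataset(reg, 2, 3, seed = 37)
  ds2 <- generate_dataset(reg, 2, 3, seed = 37)
  expect_identical(ds1$blocks, ds2$blocks)
  expect_equal(nrow(ds1$trials), 2 * 3 * length(reg))
  expect_equal(unique(table(ds1$trials$participant, ds1$trials$condition)),
               3L)
  tr <- dataset_trial(ds1, 2, "blue", 1)
  expect_s3_class(tr, "trial_timecourse")
  expect_equal(nrow(tr$samples), 3120)

  # adding participants leaves existing ones' trials unchanged
  ds3 <- generate_dataset(reg, 3, 3, seed = 37)
  expect_identical(ds1$blocks[[1]]$red$samples[1:5, 1:2],
                   ds3$blocks[[1]]$red$samples[1:5, 1:2])
})

test_that("participant gamma frequencies spread with the population SD", {
  fx <- participant_effects(30, seed = 38)
  off <- vapply(fx, `[[`, numeric(1), "freq_offset")
  expect_lt(abs(mean(off)), 0.5)
  expect_gt(sd(off), 5); expect_lt(sd(off), 11)
  gains <- vapply(fx, `[[`, numeric(1), "gain")
  expect_equal(mean(gains), 1, tolerance = 1e-12)
  # second-peak offsets are independent of the first (balanced quantiles,
  # independently permuted)
  off2 <- vapply(fx, `[[`, numeric(1), "freq2_offset")
  expect_lt(abs(cor(off, off2)), 0.5)
})
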