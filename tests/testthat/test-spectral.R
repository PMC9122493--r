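# Epoching, multitaper estimation, percent power change, band extraction and
# the time-frequency transform.

make_trial <- function(x, fs = 1200) trial_timecourse(x, fs = fs, onset_s = 1.2)

test_that("epoch segmentation matches brute-force enumeration", {
  cfg <- spectral_config()
  x <- rnorm(3120)
  tr <- make_trial(x)
  expect_equal(ncol(segment_epochs(tr, "stimulus", "low", cfg)$epochs), 3)
  expect_equal(ncol(segment_epochs(tr, "stimulus", "high", cfg)$epochs), 5)
  expect_equal(ncol(segment_epochs(tr, "baseline", "high", cfg)$epochs), 5)

  # property: epoch count equals enumerating all half-window start offsets
  set.seed(3)
  for (i in 1:20) {
    len <- sample(300:3000, 1); window <- sample(c(100, 240, 400, 600), 1)
    starts <- visgamma:::epoch_starts(len, window)
    brute <- sum((0:len) %% (window / 2) == 0 & (0:len) + window <= len)
    expect_equal(length(starts), brute)
  }

  ep <- segment_epochs(tr, "stimulus", "high", cfg)
  expect_lt(max(abs(colMeans(ep$epochs))), 1e-12)
  short <- trial_timecourse(rnorm(360), fs = 1200, onset_s = 0.1)
  expect_error(segment_epochs(short, "stimulus", "high", cfg), "shorter")
})

test_that("multitaper spectra locate sinusoids and are flat for white noise", {
  cfg <- spectral_config()
  t <- (0:1199) / 1200
  tr <- make_trial(c(rep(0, 1800), sin(2 * pi * 50 * t), rep(0, 120)) +
                     rnorm(3120, sd = 1e-3))
  ps <- epoch_power_spectrum(segment_epochs(tr, "stimulus", "high", cfg), cfg)
  expect_equal(ps$freqs_hz[which.max(ps$power)], 50)
  expect_equal(diff(ps$freqs_hz)[1], 1)

  # superposition: two half-amplitude sinusoids give two local maxima
  tr2 <- make_trial(c(rep(0, 1800),
                      0.5 * sin(2 * pi * 45 * t) + 0.5 * sin(2 * pi * 97 * t),
                      rep(0, 120)) + rnorm(3120, sd = 1e-3))
  ps2 <- epoch_power_spectrum(segment_epochs(tr2, "stimulus", "high", cfg), cfg)
  max_in <- function(lo, hi) {
    sel <- ps2$freqs_hz >= lo & ps2$freqs_hz <= hi
    ps2$freqs_hz[sel][which.max(ps2$power[sel])]
  }
  expect_equal(max_in(20, 70), 45)
  expect_equal(max_in(71, 120), 97)

  # white-noise flatness over 20-120 Hz with 1000 epochs, and total power
  # conservation: mean power equals the variance within 2%
  set.seed(9)
  E <- matrix(rnorm(400 * 4000), 400)
  eps <- structure(list(epochs = visgamma:::detrend_epochs(E),
                        window_len_s = 1 / 3, overlap = 0.5,
                        period = "stimulus", freq_band = "high", fs = 1200),
                   class = "epoch_set")
  ps3 <- epoch_power_spectrum(eps, cfg)
  band <- ps3$freqs_hz >= 20 & ps3$freqs_hz <= 120
  expect_lt(max(abs(ps3$power[band] - mean(ps3$power[band]))) /
              mean(ps3$power[band]), 0.05)
  expect_equal(mean(ps3$power[ps3$freqs_hz >= 5]), 1, tolerance = 0.02)

  expect_error(epoch_power_spectrum(structure(list(epochs = NULL),
                                              class = "epoch_set"), cfg),
               "empty")
})

test_that("percent power change is the baseline-relative difference", {
  f <- 0:140
  base <- structure(list(freqs_hz = f, power = rep(2, 141)),
                    class = "power_spectrum")
  stim <- structure(list(freqs_hz = f, power = rep(2, 141)),
                    class = "power_spectrum")
  expect_equal(power_change_spectrum(stim, base)$change_percent, rep(0, 141))
  stim$power <- base$power * 2
  expect_equal(power_change_spectrum(stim, base)$change_percent,
               rep(100, 141))
  bad <- structure(list(freqs_hz = f + 0.5, power = rep(2, 141)),
                   class = "power_spectrum")
  expect_error(power_change_spectrum(bad, base), "grids")
  base$power[3] <- 0
  expect_error(power_change_spectrum(stim, base), "positive")
})

test_that("band and bin summaries follow the averaging and rounding rules", {
  cfg <- spectral_config()
  f <- 0:140
  flat <- structure(list(freqs_hz = f, change_percent = rep(30, 141)),
                    class = "power_change_spectrum")
  expect_equal(band_power_change(flat, 50, "band", cfg), 30)
  expect_equal(band_power_change(flat, 50, "bin", cfg), 30)

  # triangular bump centered on the peak: band mean < bin value (oracle:
  # direct averaging of the triangle)
  tri <- pmax(0, 1 - abs(f - 50) / 10) * 40
  bump <- structure(list(freqs_hz = f, change_percent = tri),
                    class = "power_change_spectrum")
  expect_equal(band_power_change(bump, 50, "bin", cfg), 40)
  expect_equal(band_power_change(bump, 50, "band", cfg),
               mean(tri[f >= 40 & f <= 60]))
  expect_lt(band_power_change(bump, 50, "band", cfg),
            band_power_change(bump, 50, "bin", cfg))

  # nearest-bin rule on a 1-Hz grid: 45.4 -> 45; exact tie 45.5 -> 45
  ramp <- structure(list(freqs_hz = f, change_percent = as.numeric(f)),
                    class = "power_change_spectrum")
  expect_equal(band_power_change(ramp, 45.4, "bin", cfg), 45)
  expect_equal(band_power_change(ramp, 45.5, "bin", cfg), 45)
  expect_error(band_power_change(ramp, 130, "bin", cfg), "15-120")
})

test_that("time-frequency change localizes injected power in time and frequency", {
  cfg <- spectral_config()
  set.seed(11)
  t_ax <- (0:3119) / 1200 - 1.2
  onset <- 0.1   # injected later than stimulus onset to test localization
  x <- make_background_noise(2.6, exponent = 1)[, 1]
  amp <- 6 * sd(x)
  tr <- make_trial(x + amp * sin(2 * pi * 52 * t_ax) * (t_ax > onset))
  tf <- time_frequency(tr, cfg)
  expect_equal(diff(tf$freqs_hz)[1], 0.25)
  fi <- which.min(abs(tf$freqs_hz - 52))
  ridge <- tf$change_percent[, fi]
  # change concentrated post-onset
  expect_gt(mean(ridge[tf$time_s > onset + 0.2]),
            10 * max(1, abs(mean(ridge[tf$time_s < onset - 0.2]))))
  # ridge onset (first half-max crossing) within 50 ms of injection
  cross <- tf$time_s[which(ridge > max(ridge) / 2)[1]]
  expect_lt(abs(cross - onset), 0.05)

  # pure-noise trials: the trial-averaged change stays near zero (a small
  # positive ratio bias from the finite baseline reference is expected)
  set.seed(5)
  acc <- 0
  for (i in 1:25) {
    x0 <- make_background_noise(2.6, exponent = 1)[, 1]
    acc <- acc + time_frequency(make_trial(x0), cfg)$change_percent / 25
  }
  sel <- tf$freqs_hz >= 30 & tf$freqs_hz <= 120
  base_rows <- tf$time_s >= -1 & tf$time_s < 0
  expect_lt(abs(mean(acc[base_rows, sel])), 1e-9)
  expect_lt(abs(mean(acc[, sel])), 5)
})
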