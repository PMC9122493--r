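# 1/f-type background noise and the amplitude calibration that ties injected
# oscillations to the percent power change the spectral pipeline reports.

#' Simulate 1/f-type background noise
#'
#' Spectral-shaping synthesis: complex white Gaussian Fourier coefficients
#' are scaled by `f^(-exponent/2)` (flat below 1 Hz, zero DC) and inverse
#' transformed, so the periodogram falls as `f^(-exponent)` on log-log axes.
#' Synthesis runs on an FFT-friendly length and is truncated to the requested
#' duration.
#'
#' @param duration_s signal duration, seconds (> 0).
#' @param fs sampling rate, Hz.
#' @param exponent spectral slope magnitude, in `[0, 2]` (0 = white noise).
#' @param seed optional integer seed; the same seed reproduces the samples
#'   exactly.
#' @param n number of independent realizations.
#' @param scale multiplies the output amplitude (arbitrary units).
#' @return numeric matrix, `duration_s * fs` rows by `n` columns.
#' @export
make_background_noise <- function(duration_s, fs = 1200, exponent = 1,
                                  seed = NULL, n = 1, scale = 1) {
  if (duration_s <= 0) stopf("duration must be positive")
  check_number(exponent, "exponent", lower = 0, upper = 2)
  len <- round(duration_s * fs)
  gen <- function() noise_block(len, fs, exponent, n) * scale
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

noise_block <- function(len, fs, exponent, n) {
  L <- max(stats::nextn(len, c(2, 3, 5)), 16L)
  nf <- L %/% 2L
  f <- (1:(nf - 1)) * fs / L
  g <- pmax(f, 1)^(-exponent / 2)
  Z <- matrix(complex(real = stats::rnorm((nf - 1) * n),
                      imaginary = stats::rnorm((nf - 1) * n)) * g,
              nf - 1, n)
  spec <- rbind(matrix(0, 1, n), Z, matrix(0, 1, n), Conj(Z[(nf - 1):1, ,
                                                            drop = FALSE]))
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / sqrt(L)
  x[seq_len(len), , drop = FALSE]
}

## calibration cache ----------------------------------------------------------
## Expected spectral quantities of the standard trial under the pipeline's
## multitaper scheme, estimated once per (exponent, config) by Monte Carlo
## with a fixed internal seed, so calibration never consumes user randomness.

calib_cache <- new.env(parent = emptyenv())

calib_key <- function(exponent, cfg) {
  sprintf("%g_%d_%g_%d_%g_%g", exponent, cfg$fs, cfg$nw_high,
          cfg$n_tapers_high, cfg$pad_s, cfg$freq_max_hz)
}

# expected multitaper noise power per 1-Hz bin (unit noise scale), plus the
# mean and mean reciprocal of the low-pass-filtered baseline SD used for
# ERF z-scoring
noise_reference <- function(exponent = 1, cfg = spectral_config(),
                            n_mc = 150) {
  key <- calib_key(exponent, cfg)
  if (!is.null(calib_cache[[key]])) return(calib_cache[[key]])
  ref <- with_seed(722131L + round(1000 * exponent), {
    len <- round(cfg$fs * (cfg$stimulus[2] - cfg$stimulus[1]))
    X <- noise_block(len, cfg$fs, exponent, n_mc)
    P <- rowMeans(mt_power_block(X, cfg))
    blen <- round(cfg$fs * (cfg$baseline[2] - cfg$baseline[1]))
    B <- noise_block(blen, cfg$fs, exponent, n_mc)
    BF <- gauss_lowpass(B, cfg$fs)
    sds <- apply(BF, 2, stats::sd)
    list(power = P, freqs_hz = 0:cfg$freq_max_hz,
         mean_sd = mean(sds), mean_inv_sd = mean(1 / sds))
  })
  calib_cache[[key]] <- ref
  ref
}

# taper- and epoch-averaged power of a unit-amplitude sinusoid over the
# stimulus period, averaged over start phase; deterministic
sinusoid_reference <- function(freq_hz, cfg = spectral_config()) {
  key <- sprintf("sin_%s_%0.2f", calib_key(1, cfg), freq_hz)
  if (!is.null(calib_cache[[key]])) return(calib_cache[[key]])
  len <- round(cfg$fs * (cfg$stimulus[2] - cfg$stimulus[1]))
  t <- (0:(len - 1)) / cfg$fs
  ph <- seq(0, 2 * pi, length.out = 9)[-9]
  X <- vapply(ph, function(p) sin(2 * pi * freq_hz * t + p), numeric(len))
  P <- rowMeans(mt_power_block(X, cfg))
  calib_cache[[key]] <- P
  P
}

#' Calibrate an injected sinusoid amplitude to a target percent power change
#'
#' Returns the amplitude of a stationary sinusoid (random phase per trial)
#' such that, once added to `1/f`-type background noise during the stimulus
#' window, the spectral pipeline's percent power-change estimate equals
#' `target_percent` in expectation. `mode = "bin"` matches the change at the
#' frequency bin nearest the injected frequency; `mode = "band"` matches the
#' mean change over the gamma band (peak +/- `band_halfwidth_hz`), the
#' study-level summary measure.
#'
#' @param freq_hz sinusoid frequency, Hz.
#' @param target_percent desired percent power change (>= 0).
#' @param exponent background-noise spectral exponent.
#' @param noise_scale amplitude scale of the background noise.
#' @param mode `"band"` or `"bin"`.
#' @param cfg a [spectral_config()].
#' @return sinusoid amplitude (same units as the noise).
#' @export
calibrate_gamma_amplitude <- function(freq_hz, target_percent, exponent = 1,
                                      noise_scale = 1,
                                      mode = c("band", "bin"),
                                      cfg = spectral_config()) {
  mode <- match.arg(mode)
  if (target_percent < 0) stopf("target percent change must be non-negative")
  if (target_percent == 0) return(0)
  ref <- noise_reference(exponent, cfg)
  Pn <- ref$power * noise_scale^2
  Ps <- sinusoid_reference(freq_hz, cfg)
  f <- ref$freqs_hz
  if (mode == "bin") {
    i <- which.min(abs(f - freq_hz))
    a2 <- (target_percent / 100) * Pn[i] / Ps[i]
  } else {
    sel <- f >= freq_hz - cfg$band_halfwidth_hz &
      f <= freq_hz + cfg$band_halfwidth_hz
    a2 <- (target_percent / 100) / mean(Ps[sel] / Pn[sel])
  }
  sqrt(a2)
}

# acausal Gaussian low-pass, -6 dB amplitude at 80 Hz:
# |H(f)| = exp(-2 pi^2 sigma^2 f^2), sigma = sqrt(log(2)/2)/(pi * cutoff)
gauss_lowpass <- function(x, fs, cutoff_hz = 80) {
  sigma <- sqrt(log(2) / 2) / (pi * cutoff_hz) * fs   # in samples
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  x <- as.matrix(x)
  n <- nrow(x)
  # reflection padding keeps unit DC gain at the edges
  xp <- rbind(x[half:1, , drop = FALSE], x, x[n:(n - half + 1), , drop = FALSE])
  y <- stats::filter(xp, k, sides = 2)
  matrix(y[(half + 1):(half + n), ], n, ncol(x))
}
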