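# Multitaper spectral analysis of virtual-dipole trials.
#
# Baseline (-1.0 to 0 s) and stimulus (0.3 to 1.3 s) periods are cut into 50%
# overlapping epochs (500 ms for the low band <= 20 Hz, 333 ms above), each
# demeaned and linearly detrended, tapered (single Hann low band; three
# Slepian tapers, time-half-bandwidth NW = 1, high band), zero-padded to 1 s
# and Fourier transformed. Power is averaged over tapers and epochs; all
# tapers carry unit energy so white noise of variance v has flat expected
# power v. Percent power change is computed per frequency bin against the
# per-condition average baseline spectrum.

#' Spectral analysis configuration
#'
#' @param fs sampling rate, Hz.
#' @param baseline,stimulus period bounds in seconds relative to stimulus
#'   onset (half-open intervals).
#' @param pad_s zero-padding target in seconds (1 s gives a 1-Hz grid).
#' @param n_tapers_high number of Slepian tapers for the high band.
#' @param nw_high Slepian time-half-bandwidth product for the high band.
#' @param freq_max_hz highest frequency retained by the batched engine.
#' @param band_halfwidth_hz half-width of the gamma band summary, Hz.
#' @param fit_range_hz frequency range handed to the peak-model fit.
#' @param weighting bin-weighting scheme for the peak fit: `"scaled"`,
#'   `"uniform"` or `"softmax"`.
#' @param tf_pad_s zero-padding for the time-frequency transform, seconds.
#' @param tf_decimate keep every `tf_decimate`-th timepoint in the
#'   time-frequency transform (1 = full sampling rate).
#' @return a list of class `"spectral_config"`.
#' @export
spectral_config <- function(fs = 1200,
                            baseline = c(-1.0, 0),
                            stimulus = c(0.3, 1.3),
                            pad_s = 1,
                            n_tapers_high = 3,
                            nw_high = 1,
                            freq_max_hz = 140,
                            band_halfwidth_hz = 10,
                            fit_range_hz = c(15, 120),
                            weighting = c("scaled", "uniform", "softmax"),
                            tf_pad_s = 4,
                            tf_decimate = 12) {
  weighting <- match.arg(weighting)
  cfg <- list(fs = fs, baseline = baseline, stimulus = stimulus, pad_s = pad_s,
              n_tapers_high = n_tapers_high, nw_high = nw_high,
              freq_max_hz = freq_max_hz,
              band_halfwidth_hz = band_halfwidth_hz,
              fit_range_hz = fit_range_hz, weighting = weighting,
              tf_pad_s = tf_pad_s, tf_decimate = tf_decimate)
  class(cfg) <- "spectral_config"
  cfg
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem, whose top
#' eigenvectors are the Slepian sequences. Tapers are returned with unit
#' energy and positive mean.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product.
#' @param k number of tapers.
#' @return an `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  t <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n - t[-1]) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (sum(h[, j]) < 0) h[, j] <- -h[, j]
    h[, j] <- h[, j] / sqrt(sum(h[, j]^2))
  }
  h
}

# memoised taper/window lookup
taper_cache <- new.env(parent = emptyenv())

band_tapers <- function(freq_band, cfg) {
  if (freq_band == "high") {
    n <- round(cfg$fs / 3)
    key <- sprintf("dpss_%d_%g_%d", n, cfg$nw_high, cfg$n_tapers_high)
    if (is.null(taper_cache[[key]]))
      taper_cache[[key]] <- dpss_tapers(n, cfg$nw_high, cfg$n_tapers_high)
  } else {
    n <- round(cfg$fs / 2)
    key <- sprintf("hann_%d", n)
    if (is.null(taper_cache[[key]])) {
      h <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
      taper_cache[[key]] <- matrix(h / sqrt(sum(h^2)), ncol = 1)
    }
  }
  taper_cache[[key]]
}

epoch_starts <- function(len, window) {
  step <- window %/% 2L
  if (len < window) return(integer(0))
  seq(0L, len - window, by = step)
}

#' Trial timecourse container
#'
#' One trial's virtual-dipole signal(s) with segmentation metadata. Multiple
#' dipoles are stored as columns.
#'
#' @param samples numeric vector or samples-by-dipoles matrix.
#' @param fs sampling rate, Hz (the study digitized at 1200 Hz).
#' @param onset_s time of stimulus onset from the first sample, seconds.
#' @param condition,participant labels carried through the analysis.
#' @param dipole_signs per-dipole generative polarity (+1/-1), if known.
#' @param change_time_s time of the behavioral change event, seconds after
#'   onset (`NA` when not simulated).
#' @return an object of class `"trial_timecourse"`.
#' @export
trial_timecourse <- function(samples, fs = 1200, onset_s = 1.2,
                             condition = NA_character_, participant = NA,
                             dipole_signs = NULL, change_time_s = NA) {
  samples <- as.matrix(samples)
  structure(list(samples = samples, fs = fs, onset_s = onset_s,
                 t0_index = round(onset_s * fs) + 1L,
                 condition = condition, participant = participant,
                 dipole_signs = dipole_signs, change_time_s = change_time_s),
            class = "trial_timecourse")
}

trial_time_axis <- function(trial) {
  (seq_len(nrow(trial$samples)) - trial$t0_index) / trial$fs
}

period_rows <- function(trial, bounds) {
  t <- trial_time_axis(trial)
  which(t >= bounds[1] - 1e-12 & t < bounds[2] - 1e-12)
}

#' Segment a trial period into overlapping epochs
#'
#' Cuts the requested period into 50% overlapping windows (500 ms for the low
#' band, 333 ms for the high band), then demeans and linearly detrends each
#' epoch.
#'
#' @param trial a [trial_timecourse()] (first dipole is used).
#' @param period `"baseline"` or `"stimulus"`.
#' @param freq_band `"low"` (<= 20 Hz) or `"high"` (> 20 Hz).
#' @param cfg a [spectral_config()].
#' @return an object of class `"epoch_set"`: matrix `epochs`
#'   (window x n_epochs) plus window metadata.
#' @export
segment_epochs <- function(trial, period = c("stimulus", "baseline"),
                           freq_band = c("high", "low"),
                           cfg = spectral_config()) {
  period <- match.arg(period)
  freq_band <- match.arg(freq_band)
  rows <- period_rows(trial, if (period == "baseline") cfg$baseline else cfg$stimulus)
  window <- if (freq_band == "high") round(cfg$fs / 3) else round(cfg$fs / 2)
  if (length(rows) < window)
    stopf("%s period (%d samples) is shorter than one %d-sample window",
          period, length(rows), window)
  starts <- epoch_starts(length(rows), window)
  x <- trial$samples[rows, 1]
  E <- vapply(starts, function(s) x[s + seq_len(window)], numeric(window))
  E <- detrend_epochs(E)
  structure(list(epochs = E, window_len_s = window / cfg$fs, overlap = 0.5,
                 period = period, freq_band = freq_band, fs = cfg$fs),
            class = "epoch_set")
}

# remove per-epoch mean and least-squares line
detrend_epochs <- function(E) {
  n <- nrow(E)
  D <- cbind(1, seq_len(n) - (n + 1) / 2)
  E - D %*% solve(crossprod(D), crossprod(D, E))
}

#' Multitaper power spectrum of an epoch set
#'
#' Tapers each epoch (Hann for the low band; `n_tapers_high` Slepian tapers
#' for the high band), zero-pads to `pad_s` seconds and averages squared
#' Fourier magnitudes over tapers and epochs.
#'
#' @param epochs an [segment_epochs()] result.
#' @param cfg a [spectral_config()].
#' @return an object of class `"power_spectrum"`: `freqs_hz` (1-Hz grid from
#'   0 up to the Nyquist of the padded window) and non-negative `power`.
#' @export
epoch_power_spectrum <- function(epochs, cfg = spectral_config()) {
  E <- epochs$epochs
  if (is.null(E) || ncol(E) == 0L) stopf("epoch set is empty")
  H <- band_tapers(epochs$freq_band, cfg)
  pad <- round(cfg$fs * cfg$pad_s)
  nb <- pad %/% 2 + 1L
  P <- 0
  for (j in seq_len(ncol(H))) {
    X <- stats::mvfft(rbind(H[, j] * E, matrix(0, pad - nrow(E), ncol(E))))
    P <- P + rowMeans(Mod(X[seq_len(nb), , drop = FALSE])^2) / ncol(H)
  }
  structure(list(freqs_hz = (0:(nb - 1)) * cfg$fs / pad, power = P),
            class = "power_spectrum")
}

#' Percent power change relative to baseline
#'
#' `100 * (stimulus - baseline) / baseline` per frequency bin. The two
#' spectra must share one frequency grid and the baseline must be strictly
#' positive everywhere.
#'
#' @param stim,baseline_avg `"power_spectrum"` objects.
#' @return an object of class `"power_change_spectrum"` with `freqs_hz` and
#'   `change_percent` (bounded below by -100).
#' @export
power_change_spectrum <- function(stim, baseline_avg) {
  if (length(stim$freqs_hz) != length(baseline_avg$freqs_hz) ||
      any(abs(stim$freqs_hz - baseline_avg$freqs_hz) > 1e-9))
    stopf("stimulus and baseline spectra are on different frequency grids")
  if (any(baseline_avg$power <= 0))
    stopf("baseline power must be strictly positive in every bin")
  structure(list(freqs_hz = stim$freqs_hz,
                 change_percent = 100 * (stim$power - baseline_avg$power) /
                   baseline_avg$power),
            class = "power_change_spectrum")
}

#' Gamma-band summary of a power-change spectrum
#'
#' `mode = "band"`: mean change over the individual gamma peak +/- 10 Hz
#' (configurable half-width). `mode = "bin"`: change at the bin nearest the
#' peak frequency, ties resolved toward the lower frequency.
#'
#' @param change a `"power_change_spectrum"`.
#' @param peak_hz per-participant, per-condition gamma peak frequency; must
#'   lie within 15-120 Hz.
#' @param mode `"band"` or `"bin"`.
#' @param cfg a [spectral_config()].
#' @return scalar percent power change.
#' @export
band_power_change <- function(change, peak_hz, mode = c("band", "bin"),
                              cfg = spectral_config()) {
  mode <- match.arg(mode)
  if (peak_hz < 15 || peak_hz > 120)
    stopf("peak frequency %.1f Hz outside the supported 15-120 Hz range", peak_hz)
  f <- change$freqs_hz
  if (mode == "bin") {
    d <- abs(f - peak_hz)
    # nearest bin, ties to the lower frequency
    i <- which(d < min(d) + 1e-9)[1]
    change$change_percent[i]
  } else {
    hw <- cfg$band_halfwidth_hz
    sel <- f >= peak_hz - hw - 1e-9 & f <= peak_hz + hw + 1e-9
    if (!any(sel)) stopf("no frequency bins inside the peak band")
    mean(change$change_percent[sel])
  }
}

#' Time-frequency transform of one trial
#'
#' Slides the high-band multitaper scheme over the trial: a 333-ms epoch is
#' centered on every retained timepoint, tapered, zero-padded to `tf_pad_s`
#' seconds (0.25-Hz grid at the default 4 s) and transformed. Power is
#' converted to percent change against the per-frequency average over
#' baseline timepoints.
#'
#' @param trial a [trial_timecourse()] (first dipole is used).
#' @param cfg a [spectral_config()]; `tf_decimate` controls the output rate.
#' @return list with `time_s`, `freqs_hz` and `change_percent`
#'   (time x frequency matrix).
#' @export
time_frequency <- function(trial, cfg = spectral_config()) {
  H <- band_tapers("high", cfg)
  window <- nrow(H)
  half <- window %/% 2
  x <- trial$samples[, 1]
  t_ax <- trial_time_axis(trial)
  centers <- seq(half + 1L, length(x) - half, by = cfg$tf_decimate)
  E <- vapply(centers, function(c0) x[(c0 - half):(c0 + half - 1L)],
              numeric(window))
  E <- detrend_epochs(E)
  pad <- round(cfg$fs * cfg$tf_pad_s)
  nb_keep <- sum((0:(pad %/% 2)) * cfg$fs / pad <= cfg$freq_max_hz)
  freqs <- (0:(nb_keep - 1)) * cfg$fs / pad
  P <- 0
  for (j in seq_len(ncol(H))) {
    W <- exp(-2i * pi * outer(freqs / cfg$fs, 0:(window - 1)))
    W <- W * rep(H[, j], each = nrow(W))
    Z <- W %*% E
    P <- P + (Re(Z)^2 + Im(Z)^2) / ncol(H)
  }
  tc <- t_ax[centers]
  base <- tc >= cfg$baseline[1] & tc < cfg$baseline[2]
  if (!any(base)) stopf("no time-frequency windows fall inside the baseline")
  ref <- rowMeans(P[, base, drop = FALSE])
  list(time_s = tc, freqs_hz = freqs,
       change_percent = t(100 * (P - ref) / ref))
}

## ---- batched engine (internal) --------------------------------------------
## Power spectra for many trials/dipoles at once. X is a samples-by-signals
## matrix holding one full period per column; the result is the per-column
## taper- and epoch-averaged power on an integer-Hz grid up to freq_max_hz.

spectral_weight_matrices <- function(cfg) {
  key <- sprintf("W_%d_%g_%d_%g_%g", round(cfg$fs / 3), cfg$nw_high,
                 cfg$n_tapers_high, cfg$pad_s, cfg$freq_max_hz)
  if (is.null(taper_cache[[key]])) {
    window <- round(cfg$fs / 3)
    H <- band_tapers("high", cfg)
    pad <- round(cfg$fs * cfg$pad_s)
    freqs <- 0:cfg$freq_max_hz
    ph <- -2 * pi * outer(freqs * pad / cfg$fs, 0:(window - 1)) / pad
    taper_cache[[key]] <- lapply(seq_len(ncol(H)), function(j) {
      list(re = cos(ph) * rep(H[, j], each = nrow(ph)),
           im = sin(ph) * rep(H[, j], each = nrow(ph)))
    })
  }
  taper_cache[[key]]
}

mt_power_block <- function(X, cfg) {
  window <- round(cfg$fs / 3)
  starts <- epoch_starts(nrow(X), window)
  M <- ncol(X)
  E <- do.call(cbind, lapply(starts, function(s) X[s + seq_len(window), ,
                                                   drop = FALSE]))
  E <- detrend_epochs(E)
  Wl <- spectral_weight_matrices(cfg)
  P <- 0
  for (w in Wl) P <- P + ((w$re %*% E)^2 + (w$im %*% E)^2) / length(Wl)
  # average the epoch blocks (columns are grouped by epoch start)
  acc <- P[, seq_len(M), drop = FALSE]
  for (j in seq_along(starts)[-1])
    acc <- acc + P[, (j - 1) * M + seq_len(M), drop = FALSE]
  acc / length(starts)
}
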