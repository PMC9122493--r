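# Event-related field processing.
#
# Virtual-dipole traces are low-pass filtered with an acausal Gaussian kernel
# (-6 dB amplitude at 80 Hz), z-scored against the per-trial baseline
# (default -1.0 to 0 s, computed before cutting), cut to -0.2 to 0.6 s and
# averaged. Dipoles whose all-condition average is positive-going during the
# N70 window (55-95 ms) are sign-flipped, one sign per dipole for all
# conditions. N70 features: peak time = minimum of the condition-average
# trace in 50-110 ms; slope = least-squares line over 2-12 ms before the
# peak; per-trial amplitude = mean over peak +/- 10 ms.

erf_window_s <- c(-0.2, 0.6)
n70_search_ms <- c(50, 110)
flip_window_ms <- c(55, 95)

#' Low-pass filter and baseline z-score a trial
#'
#' @param trial a [trial_timecourse()]; must cover -0.2 to 0.6 s.
#' @param cfg a [spectral_config()] (supplies the sampling rate and baseline
#'   window).
#' @param cutoff_hz -6 dB amplitude point of the Gaussian kernel.
#' @param baseline z-scoring window in seconds relative to onset; defaults
#'   to the spectral baseline window.
#' @return an object of class `"erf_trace"`: matrix `samples`
#'   (timepoints x dipoles, z units) and `time_ms`.
#' @export
lowpass_zscore <- function(trial, cfg = spectral_config(), cutoff_hz = 80,
                           baseline = NULL) {
  t_ax <- trial_time_axis(trial)
  if (min(t_ax) > erf_window_s[1] + 1e-9 || max(t_ax) < erf_window_s[2] - 1e-9)
    stopf("trial does not cover the %g to %g s ERF window",
          erf_window_s[1], erf_window_s[2])
  baseline <- baseline %||% cfg$baseline
  y <- gauss_lowpass(trial$samples, trial$fs, cutoff_hz)
  brows <- which(t_ax >= baseline[1] - 1e-12 & t_ax < baseline[2] - 1e-12)
  mu <- colMeans(y[brows, , drop = FALSE])
  sd <- apply(y[brows, , drop = FALSE], 2, stats::sd)
  if (any(sd <= 0)) stopf("zero baseline variance; cannot z-score")
  z <- sweep(sweep(y, 2, mu), 2, sd, "/")
  keep <- which(t_ax >= erf_window_s[1] - 1e-12 & t_ax <= erf_window_s[2] + 1e-12)
  structure(list(samples = z[keep, , drop = FALSE],
                 time_ms = t_ax[keep] * 1000),
            class = "erf_trace")
}

#' Determine per-dipole polarity flips
#'
#' One sign per dipole, shared by all conditions: -1 where the all-condition
#' average trace has positive mean in the 55-95 ms N70 window, else +1.
#'
#' @param traces list of `"erf_trace"` objects (all of one participant's
#'   trials, across conditions).
#' @return numeric vector of +/-1, one per dipole.
#' @export
determine_flip_signs <- function(traces) {
  if (!length(traces)) stopf("need at least one trial per dipole")
  acc <- 0
  for (tr in traces) acc <- acc + tr$samples
  avg <- acc / length(traces)
  tm <- traces[[1]]$time_ms
  win <- tm >= flip_window_ms[1] & tm <= flip_window_ms[2]
  ifelse(colMeans(avg[win, , drop = FALSE]) > 0, -1, 1)
}

#' N70 features of a condition-average ERF
#'
#' @param avg_trace `"erf_trace"` holding the condition-average trace
#'   (dipole-averaged: one column).
#' @param trial_traces optional list of per-trial `"erf_trace"`s (dipole
#'   averaged) from which per-trial amplitudes are extracted.
#' @return an object of class `"n70_features"`: `peak_time_ms`,
#'   `amplitude_z` (mean over peak +/- 10 ms of the average trace),
#'   `slope_z_per_ms` (line slope over 2-12 ms pre-peak), `edge_flag`
#'   (peak at the search-window boundary), `degenerate_flag` (flat trace)
#'   and `trial_amplitudes`.
#' @export
n70_features <- function(avg_trace, trial_traces = NULL) {
  tm <- avg_trace$time_ms
  x <- avg_trace$samples[, 1]
  if (min(tm) > 40 || max(tm) < 120)
    stopf("trace must cover 40-120 ms")
  sel <- which(tm >= n70_search_ms[1] & tm <= n70_search_ms[2])
  i <- sel[which.min(x[sel])]
  peak_ms <- tm[i]
  edge <- i == sel[1] || i == sel[length(sel)]
  degenerate <- stats::sd(x[sel]) < 1e-12
  win <- which(tm >= peak_ms - 10 & tm <= peak_ms + 10)
  amp <- mean(x[win])
  pre <- which(tm >= peak_ms - 12 & tm <= peak_ms - 2)
  slope <- unname(stats::coef(stats::lm(x[pre] ~ tm[pre]))[2])
  trial_amp <- if (!is.null(trial_traces))
    vapply(trial_traces, function(tr) mean(tr$samples[win, 1]), numeric(1))
  structure(list(peak_time_ms = peak_ms, amplitude_z = amp,
                 slope_z_per_ms = slope, edge_flag = edge,
                 degenerate_flag = degenerate,
                 trial_amplitudes = trial_amp),
            class = "n70_features")
}

#' @export
print.n70_features <- function(x, ...) {
  cat(sprintf("N70: peak %.1f ms, amplitude %.3f z, slope %.4f z/ms%s\n",
              x$peak_time_ms, x$amplitude_z, x$slope_z_per_ms,
              if (x$edge_flag) " [edge]" else ""))
  invisible(x)
}
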