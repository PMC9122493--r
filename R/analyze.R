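# Per-participant analysis: spectral power change, peak-model selection,
# fallback peak frequencies, gamma-band extraction, and ERF/N70 features.
# Operates on one participant's condition blocks so that study-scale runs
# can stream participants without materializing the whole dataset.

erf_store_ms <- c(25, 135)  # per-trial traces retained around the N70

# Trials whose behavioral change occurs before this time (seconds after
# stimulus onset) are removed from analysis, mirroring the trial-rejection
# rule of the paradigm.
change_cutoff_s <- 1.3

analyze_participant_blocks <- function(blocks, cfg = spectral_config(),
                                       min_change_s = change_cutoff_s) {
  conds <- names(blocks)
  fs <- cfg$fs
  stim_spec <- list(); base_spec <- list()
  erf_dipole_mean <- list(); erf_trial <- list()
  n_used <- integer(length(conds))

  for (ci in seq_along(conds)) {
    bl <- blocks[[ci]]
    t_ax <- (seq_len(nrow(bl$samples)) - 1) / fs - bl$onset_s
    srows <- which(t_ax >= cfg$stimulus[1] - 1e-12 & t_ax < cfg$stimulus[2] - 1e-12)
    brows <- which(t_ax >= cfg$baseline[1] - 1e-12 & t_ax < cfg$baseline[2] - 1e-12)

    # spectral path: only trials whose behavioral change falls late enough
    # that the stimulus analysis window is unaffected
    keep <- which(bl$change_time_s >= min_change_s | is.na(bl$change_time_s))
    if (!length(keep)) stopf("condition %s: no trials survive the change-time cut",
                             conds[ci])
    n_used[ci] <- length(keep)
    cols <- as.vector(outer(seq_len(bl$n_dipoles),
                            (keep - 1) * bl$n_dipoles, "+"))
    stim_spec[[ci]] <- rowMeans(mt_power_block(bl$samples[srows, cols,
                                                          drop = FALSE], cfg))
    base_spec[[ci]] <- rowMeans(mt_power_block(bl$samples[brows, cols,
                                                          drop = FALSE], cfg))

    # ERF path (all trials): filter, z-score per trial/dipole on the
    # baseline window, keep per-dipole means and a compact per-trial cube
    frows <- which(t_ax >= cfg$baseline[1] - 1e-12 &
                     t_ax <= erf_window_s[2] + 1e-12)
    Y <- gauss_lowpass(bl$samples[frows, , drop = FALSE], fs)
    tf <- t_ax[frows]
    bsub <- which(tf >= cfg$baseline[1] - 1e-12 & tf < cfg$baseline[2] - 1e-12)
    mu <- colMeans(Y[bsub, , drop = FALSE])
    sdv <- sqrt(colMeans(Y[bsub, , drop = FALSE]^2) - mu^2) *
      sqrt(length(bsub) / (length(bsub) - 1))
    Z <- sweep(sweep(Y, 2, mu), 2, pmax(sdv, .Machine$double.eps), "/")
    erows <- which(tf >= erf_window_s[1] - 1e-12 & tf <= erf_window_s[2] + 1e-12)
    Zc <- Z[erows, , drop = FALSE]
    nd <- bl$n_dipoles; nt <- bl$n_trials
    dim(Zc) <- c(length(erows), nd, nt)
    erf_dipole_mean[[ci]] <- rowMeans(Zc, dims = 2)      # time x dipole
    crows <- which(tf[erows] >= erf_store_ms[1] / 1000 - 1e-12 &
                     tf[erows] <= erf_store_ms[2] / 1000 + 1e-12)
    erf_trial[[ci]] <- Zc[crows, , , drop = FALSE]       # time x dipole x trial
  }
  erf_time_ms <- {
    t_ax <- (seq_len(nrow(blocks[[1]]$samples)) - 1) / fs - blocks[[1]]$onset_s
    t_ax[t_ax >= erf_window_s[1] - 1e-12 & t_ax <= erf_window_s[2] + 1e-12] * 1000
  }

  # one flip sign per dipole, from the all-condition average
  all_avg <- Reduce(`+`, erf_dipole_mean) / length(erf_dipole_mean)
  win <- erf_time_ms >= flip_window_ms[1] & erf_time_ms <= flip_window_ms[2]
  signs <- ifelse(colMeans(all_avg[win, , drop = FALSE]) > 0, -1, 1)

  # spectral: change spectra against the per-condition average baseline
  fits <- stats::setNames(vector("list", length(conds)), conds)
  for (ci in seq_along(conds)) {
    chg <- list(freqs_hz = 0:cfg$freq_max_hz,
                change_percent = 100 * (stim_spec[[ci]] - base_spec[[ci]]) /
                  base_spec[[ci]])
    class(chg) <- "power_change_spectrum"
    fits[[ci]] <- peak_fit(chg, cfg)
    attr(fits[[ci]], "change") <- chg
  }
  fb <- fallback_peak_frequency(fits)

  spec_rows <- lapply(seq_along(conds), function(ci) {
    chg <- attr(fits[[ci]], "change")
    pk <- fb$peak_hz[ci]
    band <- if (is.na(pk)) NA_real_ else
      band_power_change(chg, min(max(pk, 15), 120), mode = "band", cfg = cfg)
    bin <- if (is.na(pk)) NA_real_ else
      band_power_change(chg, min(max(pk, 15), 120), mode = "bin", cfg = cfg)
    data.frame(condition = conds[ci], model = fits[[ci]]$model,
               peak_hz = pk, fallback = fb$fallback[ci],
               second_peak_hz = peak_frequency(fits[[ci]], "high"),
               band_change = band, bin_change = bin,
               adj_r2 = max(fits[[ci]]$adj_r2), n_trials = n_used[ci])
  })

  erf_rows <- lapply(seq_along(conds), function(ci) {
    avg <- rowMeans(sweep(erf_dipole_mean[[ci]], 2, signs, "*"))
    avg_trace <- structure(list(samples = matrix(avg, ncol = 1),
                                time_ms = erf_time_ms), class = "erf_trace")
    feats <- n70_features(avg_trace)
    cube <- erf_trial[[ci]]
    ct_ms <- erf_time_ms[erf_time_ms >= erf_store_ms[1] - 1e-9 &
                           erf_time_ms <= erf_store_ms[2] + 1e-9]
    wsel <- which(ct_ms >= feats$peak_time_ms - 10 &
                    ct_ms <= feats$peak_time_ms + 10)
    flip_cube <- sweep(cube, 2, signs, "*")
    trial_amp <- apply(flip_cube[wsel, , , drop = FALSE], 3, mean)
    data.frame(condition = conds[ci], n70_peak_ms = feats$peak_time_ms,
               n70_amp = mean(trial_amp), n70_slope = feats$slope_z_per_ms,
               n70_avg_amp = feats$amplitude_z,
               edge_flag = feats$edge_flag)
  })

  list(spectral = do.call(rbind, spec_rows),
       erf = do.call(rbind, erf_rows),
       flip_signs = signs,
       fits = fits,
       peakless = isTRUE(attr(fb, "peakless")))
}

#' Analyze a synthetic dataset
#'
#' Runs the spectral, peak-fit and ERF pipelines over every participant of a
#' materialized [generate_dataset()] result.
#'
#' @param dataset a `"synthetic_dataset"`.
#' @param cfg a [spectral_config()].
#' @param min_change_s trials with behavioral changes earlier than this are
#'   excluded from analysis (set to `-Inf` to keep all trials).
#' @return list with per-participant-condition `spectral` and `erf` tables
#'   (data.frames with a `participant` column) and per-participant flip
#'   signs.
#' @export
analyze_dataset <- function(dataset, cfg = NULL,
                            min_change_s = change_cutoff_s) {
  cfg <- cfg %||% dataset$cfg
  spec <- list(); erf <- list(); signs <- list()
  for (p in seq_len(dataset$n_participants)) {
    res <- analyze_participant_blocks(dataset$blocks[[p]], cfg, min_change_s)
    res$spectral$participant <- p
    res$erf$participant <- p
    spec[[p]] <- res$spectral; erf[[p]] <- res$erf
    signs[[p]] <- res$flip_signs
  }
  list(spectral = do.call(rbind, spec), erf = do.call(rbind, erf),
       flip_signs = signs)
}
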