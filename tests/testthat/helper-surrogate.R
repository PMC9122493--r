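# Gaussian-process surrogates for null power-change spectra at the study's
# dipole-averaged noise level. A change spectrum is a mean over
# n_trials x n_dipoles independent segment-sets; its law is Gaussian to
# O(1/sqrt(K)) with K ~ 3000, so surrogates drawn from the empirical mean
# and covariance of single-segment-set change contributions reproduce the
# pipeline's spectra essentially exactly while costing microseconds each.
# (helper-fixtures.R provides fix_env.)

surrogate_factor <- function(n_ref = 500, seed = 101) {
  if (!is.null(fix_env$surr)) return(fix_env$surr)
  cfg <- spectral_config()
  set.seed(seed)
  X <- visgamma:::noise_block(3120, 1200, 1, n_ref)
  t_ax <- (0:3119) / 1200 - 1.2
  S <- visgamma:::mt_power_block(
    X[t_ax >= 0.3 - 1e-12 & t_ax < 1.3 - 1e-12, ], cfg)
  B <- visgamma:::mt_power_block(
    X[t_ax >= -1 - 1e-12 & t_ax < 0 - 1e-12, ], cfg)
  D <- 100 * (S - B) / rowMeans(B)
  sel <- which((0:140) >= 15 & (0:140) <= 120)
  Sg <- stats::cov(t(D[sel, ]))
  fix_env$surr <- list(L = chol(Sg + diag(1e-10, nrow(Sg))), Sg = Sg,
                       freqs = (0:140)[sel])
  fix_env$surr
}

# n null spectra at the default study noise level (28 analyzed trials x 106
# dipoles per condition); returns bins x n matrix over 15-120 Hz
null_change_surrogates <- function(n, seed, n_segment_sets = 28 * 106) {
  sf <- surrogate_factor()
  set.seed(seed)
  t(sf$L) %*% matrix(stats::rnorm(nrow(sf$L) * n), nrow(sf$L)) /
    sqrt(n_segment_sets)
}
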