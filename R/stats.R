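# Group-level statistics: one-way repeated-measures ANOVA with
# Greenhouse-Geisser correction, Holm-corrected pairwise t-tests, JZS Bayes
# factors, nonparametric bootstrap CIs, t-max permutation-corrected
# correlation courses, and per-participant residualization of gamma power on
# N70 features.

as_subject_condition <- function(table) {
  if (is.matrix(table)) return(table)
  if (is.data.frame(table) &&
      all(c("participant", "condition", "value") %in% names(table))) {
    m <- tapply(table$value, list(table$participant, table$condition), mean)
    if (anyNA(m)) stopf("table is unbalanced: every participant needs every condition")
    return(m)
  }
  stopf("expected a participants x conditions matrix or a long data.frame")
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject F test across conditions; the sphericity
#' correction factor epsilon is computed from the double-centered sample
#' covariance of condition scores, and both degrees of freedom are scaled by
#' it before the p value is evaluated.
#'
#' @param table participants x conditions matrix (or long data.frame with
#'   columns `participant`, `condition`, `value`); must be balanced with at
#'   least 3 participants and 2 conditions.
#' @return list with `F`, `df1`, `df2` (epsilon-corrected), `p`, `epsilon`
#'   and the uncorrected degrees of freedom.
#' @export
rm_anova_gg <- function(table) {
  Y <- as_subject_condition(table)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 3 || k < 2) stopf("need >= 3 participants and >= 2 conditions")
  cond_means <- colMeans(Y)
  subj_means <- rowMeans(Y)
  grand <- mean(Y)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- Y - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fval <- (ss_cond / df1) / (ss_err / df2)
  S <- stats::cov(Y)
  C <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  eps <- sum(diag(C))^2 / ((k - 1) * sum(C^2))
  eps <- min(max(eps, 1 / (k - 1)), 1)
  list(F = Fval, df1 = eps * df1, df2 = eps * df2,
       p = stats::pf(Fval, eps * df1, eps * df2, lower.tail = FALSE),
       epsilon = eps, df1_uncorrected = df1, df2_uncorrected = df2)
}

#' Holm-corrected pairwise paired t-tests
#'
#' @param table participants x conditions matrix (or long data.frame).
#' @param pairs list of length-2 character vectors of condition names;
#'   defaults to all pairs.
#' @return data.frame with one row per pair: `a`, `b`, `t`, `df`, `p_raw`,
#'   `p_holm`.
#' @export
holm_pairwise <- function(table, pairs = NULL) {
  Y <- as_subject_condition(table)
  cn <- colnames(Y) %||% as.character(seq_len(ncol(Y)))
  colnames(Y) <- cn
  if (is.null(pairs))
    pairs <- utils::combn(cn, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    tt <- stats::t.test(Y[, pr[1]], Y[, pr[2]], paired = TRUE)
    data.frame(a = pr[1], b = pr[2], t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out
}

#' JZS Bayes factor for a one-sample or paired t statistic
#'
#' Jeffreys-Zellner-Siow default Bayes factor with a Cauchy prior of scale
#' `rscale` on the standardized effect size, computed by numerical
#' integration over the prior on the effect variance. Returns evidence for
#' the null: `BF01 > 1` favors no effect.
#'
#' @param t observed t statistic.
#' @param n sample size (pairs for a paired test); `n >= 2`.
#' @param rscale Cauchy prior scale (default 1).
#' @return the Bayes factor BF01 (null over alternative).
#' @export
jzs_bayes_factor <- function(t, n, rscale = 1) {
  if (n < 2) stopf("need n >= 2")
  nu <- n - 1
  like_h0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      sqrt(rscale^2 / 2) / gamma(1 / 2) * g^(-3 / 2) *
      exp(-rscale^2 / (2 * g))
  }
  q <- tryCatch(stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                                 subdivisions = 500L),
                error = function(e) NULL)
  if (is.null(q) || q$message != "OK")
    stopf("JZS quadrature did not converge")
  like_h0 / q$value
}

#' Nonparametric bootstrap confidence interval
#'
#' Percentile interval of a resampled statistic.
#'
#' @param values numeric vector (>= 2 values).
#' @param stat statistic function (default [mean()]).
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed optional integer seed for reproducibility.
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, stat = mean, B = 10000, level = 0.95,
                         seed = NULL) {
  n <- length(values)
  if (n < 2) stopf("need at least two values")
  run <- function() {
    reps <- if (identical(stat, mean)) {
      colMeans(matrix(values[sample.int(n, n * B, replace = TRUE)], n, B))
    } else {
      vapply(seq_len(B), function(b)
        stat(values[sample.int(n, n, replace = TRUE)]), numeric(1))
    }
    stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  }
  ci <- if (is.null(seed)) run() else with_seed(seed, run())
  stats::setNames(ci, c("lo", "hi"))
}

#' t-max permutation-corrected correlation course
#'
#' Takes per-participant correlation courses (e.g., the per-timepoint
#' across-condition correlation between an ERF value and behavioral
#' performance), Fisher-z transforms them, and tests each bin's group mean
#' against zero with a one-sample t. Familywise error across bins is
#' controlled with the permutation distribution of the maximum absolute t
#' under random per-participant sign flips.
#'
#' @param courses participants x bins matrix of correlation coefficients.
#' @param n_perm number of sign-flip permutations (>= 100); if at most
#'   `2^participants`, all distinct flips are enumerated exactly.
#' @param seed integer seed for the random permutations.
#' @param alpha familywise alpha.
#' @param fisher apply the Fisher z transform before the t test (set to
#'   `FALSE` to average raw correlations).
#' @return an object of class `"correlation_course"`: per-bin `r` (mean raw
#'   correlation), `t`, `significant`, and the permutation threshold
#'   `t_crit`.
#' @export
tmax_correlation <- function(courses, n_perm = 1000, seed = 1, alpha = 0.05,
                             fisher = TRUE) {
  courses <- as.matrix(courses)
  n <- nrow(courses); nb <- ncol(courses)
  if (n < 2 || nb < 2) stopf("need >= 2 participants and >= 2 bins")
  if (n_perm < 100) stopf("need at least 100 permutations")
  Z <- if (fisher) atanh(pmin(pmax(courses, -1 + 1e-12), 1 - 1e-12))
  else courses
  tstat <- function(M) {
    mu <- colMeans(M)
    se <- apply(M, 2, stats::sd) / sqrt(n)
    mu / pmax(se, .Machine$double.eps)
  }
  t_obs <- tstat(Z)
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tmax <- apply(signs, 1, function(s) max(abs(tstat(Z * s))))
  } else {
    tmax <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      max(abs(tstat(Z * s)))
    }, numeric(1)))
  }
  t_crit <- stats::quantile(tmax, 1 - alpha, names = FALSE, type = 1)
  structure(list(r = colMeans(courses), t = t_obs,
                 significant = abs(t_obs) > t_crit, t_crit = t_crit,
                 tmax_distribution = tmax),
            class = "correlation_course")
}

#' Residualize gamma power on N70 slope and amplitude
#'
#' Per participant, ordinary least squares of the per-condition gamma power
#' on an intercept, the N70 slope and the N70 amplitude; returns the
#' residuals per condition.
#'
#' @param gamma,n70_slope,n70_amp numeric vectors over conditions (one
#'   participant), length >= 3.
#' @return residual vector, orthogonal to both regressors.
#' @export
residualize_gamma <- function(gamma, n70_slope, n70_amp) {
  k <- length(gamma)
  if (k < 3) stopf("need at least 3 conditions (2 regressors + intercept)")
  X <- cbind(1, n70_slope, n70_amp)
  if (qr(X)$rank < 3) stopf("rank-deficient design: regressors are collinear")
  unname(stats::lm.fit(X, gamma)$residuals)
}
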