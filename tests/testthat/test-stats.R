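# Statistical layer: RM-ANOVA with Greenhouse-Geisser correction, Holm
# pairwise tests, JZS Bayes factors, bootstrap CIs, t-max correction and
# gamma residualization.

test_that("repeated-measures ANOVA matches the worked oracle", {
  # toy 4 x 3 table; F cross-checked against aov(y ~ cond + Error(subj/cond))
  # and epsilon against the definitional double-centered covariance formula
  Y <- matrix(c(1, 2, 4,
                2, 4, 5,
                3, 3, 6,
                2, 5, 8), nrow = 4, byrow = TRUE)
  res <- rm_anova_gg(Y)
  expect_equal(res$F, 17.68966, tolerance = 1e-5)
  expect_equal(res$epsilon, 0.8133462, tolerance = 1e-6)
  expect_equal(res$df1, res$epsilon * 2)
  expect_equal(res$df2, res$epsilon * 6)
  expect_equal(res$p,
               pf(res$F, res$df1, res$df2, lower.tail = FALSE))

  # exactly identical condition means (noise centered per condition) with
  # pure subject offsets: F = 0, p = 1
  set.seed(1)
  noise <- scale(matrix(rnorm(24), 6), scale = FALSE)
  Y0 <- outer(rnorm(6), rep(1, 4)) + noise
  res0 <- rm_anova_gg(Y0)
  expect_lt(res0$F, 1e-20)
  expect_gt(res0$p, 0.999)

  # compound-symmetric data satisfy sphericity: epsilon near 1 at n = 30
  set.seed(4)
  Ycs <- outer(rnorm(30, sd = 2), rep(1, 4)) + matrix(rnorm(120), 30)
  expect_gt(rm_anova_gg(Ycs)$epsilon, 0.9)

  expect_error(rm_anova_gg(data.frame(participant = c(1, 1, 2),
                                      condition = c("a", "b", "a"),
                                      value = 1:3)), "unbalanced")
})

test_that("Holm correction steps down and dominates raw p values", {
  set.seed(8)
  Y <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  Y[, 2] <- Y[, 2] + 2
  one <- holm_pairwise(Y, pairs = list(c("a", "b")))
  expect_equal(one$p_holm, one$p_raw)

  # hand step-down oracle for raw p (0.01, 0.02, 0.9):
  # sorted: 0.01*3 = 0.03; max(0.03, 0.02*2) = 0.04; max(0.04, 0.9) = 0.9
  expect_equal(p.adjust(c(0.01, 0.02, 0.9), "holm"), c(0.03, 0.04, 0.9))

  all_pairs <- holm_pairwise(Y)
  expect_equal(nrow(all_pairs), 6)
  expect_true(all(all_pairs$p_holm >= all_pairs$p_raw - 1e-15))
  expect_true(all(all_pairs$p_holm <= 1))
  # adjusted values agree with p.adjust on the raw vector
  expect_equal(all_pairs$p_holm, p.adjust(all_pairs$p_raw, "holm"))
})

test_that("JZS Bayes factor matches quadrature oracle and the known example", {
  # fine-trapezoid oracle (200k-point grid on g/(1+g)) frozen values
  expect_equal(jzs_bayes_factor(0.135, 30), 7.017707, tolerance = 1e-3)
  expect_equal(jzs_bayes_factor(1.5, 20), 2.099487, tolerance = 1e-3)

  # t = 0 favors the null; evidence decreases monotonically in |t|
  expect_gt(jzs_bayes_factor(0, 25), 1)
  bf <- vapply(seq(0, 4, by = 0.5), jzs_bayes_factor, numeric(1), n = 25)
  expect_true(all(diff(bf) < 0))
})

test_that("bootstrap CI is degenerate for constants and matches normal theory", {
  expect_equal(unname(bootstrap_ci(rep(3, 10), seed = 1)), c(3, 3))

  set.seed(2)
  x <- rnorm(1000)
  ci <- bootstrap_ci(x, B = 4000, seed = 3)
  half <- diff(unname(ci)) / 2
  expect_equal(half, 1.96 / sqrt(1000), tolerance = 0.2)
  # reproducible under the same seed
  expect_identical(bootstrap_ci(x, B = 500, seed = 9),
                   bootstrap_ci(x, B = 500, seed = 9))
  expect_error(bootstrap_ci(1), "at least two")
})

test_that("t-max correction agrees with exhaustive sign-flip enumeration", {
  set.seed(6)
  courses <- matrix(rnorm(8 * 2, sd = 0.3), 8, 2)
  res <- tmax_correlation(courses, n_perm = 1000, seed = 1)

  # independent brute force over all 2^8 sign patterns
  Z <- atanh(courses)
  tfun <- function(M) colMeans(M) / (apply(M, 2, sd) / sqrt(8))
  grid <- expand.grid(rep(list(c(-1, 1)), 8))
  tmax <- apply(grid, 1, function(s) max(abs(tfun(Z * as.numeric(s)))))
  crit <- quantile(tmax, 0.95, type = 1, names = FALSE)
  expect_equal(res$t_crit, crit)
  expect_equal(res$significant, abs(tfun(Z)) > crit)

  # a strong common correlation among null bins is detected
  set.seed(13)
  hits <- 0
  for (r in 1:30) {
    M <- matrix(rnorm(12 * 20, sd = 0.25), 12, 20)
    M[, 7] <- 0.8 + rnorm(12, sd = 0.1)
    M <- pmin(M, 0.99)
    hits <- hits + tmax_correlation(M, n_perm = 500, seed = r)$significant[7]
  }
  expect_gte(hits / 30, 0.9)
  expect_error(tmax_correlation(courses, n_perm = 50), "100")
})

test_that("gamma residualization is an exact OLS projection", {
  set.seed(10)
  slope <- rnorm(8); amp <- rnorm(8)
  # gamma exactly linear in the regressors -> zero residuals
  g1 <- 2 + 3 * amp - slope
  expect_lt(max(abs(residualize_gamma(g1, slope, amp))), 1e-10)

  # independent gamma -> residuals equal the projection-matrix result
  g2 <- rnorm(8)
  X <- cbind(1, slope, amp)
  proj <- g2 - X %*% solve(crossprod(X), crossprod(X, g2))
  r2 <- residualize_gamma(g2, slope, amp)
  expect_equal(r2, as.numeric(proj), tolerance = 1e-10)
  # orthogonality to both regressors
  expect_lt(abs(sum(r2 * slope)), 1e-10)
  expect_lt(abs(sum(r2 * amp)), 1e-10)

  expect_error(residualize_gamma(g2, slope, slope), "collinear")
  expect_error(residualize_gamma(1:2, 1:2, 2:3), "at least 3")
})

test_that("null RM-ANOVA + Holm chain keeps its nominal error rate", {
  set.seed(14)
  reject <- 0
  for (r in 1:300) {
    Y <- outer(rnorm(12), rep(1, 4)) + matrix(rnorm(48), 12)
    an <- rm_anova_gg(Y)
    if (an$p < 0.05) {
      hp <- holm_pairwise(Y)
      reject <- reject + any(hp$p_holm < 0.05)
    }
  }
  # chained familywise rate at or below alpha, within simulation error
  expect_lte(reject / 300, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 300))
})
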