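# DKL calibration chain: excitation integration, opponent projection,
# normalization constants, gamut-filling ellipse, and the inverse chain.

test_that("cone excitation integrates radiance against the fundamentals", {
  fund <- fixture_fundamentals()
  # zero radiance -> zero excitation
  z <- cone_excitation(spd(400:700, rep(0, 301)), fund)
  expect_equal(unclass(z), c(L = 0, M = 0, S = 0))

  # narrow unit-area impulse at 500 nm -> each fundamental evaluated there
  wl <- seq(498, 502, by = 0.1)
  tri <- pmax(1 - abs(wl - 500) / 1, 0)
  tri <- tri / sum(diff(wl) * (tri[-1] + tri[-length(tri)]) / 2)
  ex <- cone_excitation(spd(wl, tri), fund)
  look <- vapply(c("L", "M", "S"), function(k)
    stats::approx(fund$wavelengths_nm, fund[[k]], xout = 500)$y, numeric(1))
  expect_equal(unname(unclass(ex)), unname(look), tolerance = 2e-3)

  # linearity: excitation(a + b) = excitation(a) + excitation(b)
  set.seed(1)
  ra <- runif(301); rb <- runif(301)
  ga <- cone_excitation(spd(400:700, ra), fund)
  gb <- cone_excitation(spd(400:700, rb), fund)
  gab <- cone_excitation(spd(400:700, ra + rb), fund)
  expect_equal(unclass(gab), unclass(ga) + unclass(gb), tolerance = 1e-10)
  g2a <- cone_excitation(spd(400:700, 2 * ra), fund)
  expect_equal(unclass(g2a), 2 * unclass(ga), tolerance = 1e-10)

  expect_error(cone_excitation(spd(900:950, rep(1, 51)), fund), "overlap")
  expect_error(spd(400:500, c(rep(1, 100), -1)), "non-negative")
})

test_that("unit pooled contrast on each cardinal axis maps to unit coordinate", {
  bg <- cone_excitation_values(1, 1, 1)
  cal <- dkl_calibration(bg)
  expect_equal(unname(unclass(to_dkl(bg, cal))), c(0, 0, 0))

  # root-finding oracle: scale each axis direction (in contrast space) until
  # pooled cone contrast is exactly 1, then project
  axis_stim <- function(direction, target) {
    f <- function(t) pooled_cone_contrast(
      cone_excitation_values(1 + t * direction[1], 1 + t * direction[2],
                             1 + t * direction[3]), bg) - target
    t1 <- stats::uniroot(f, c(1e-6, 0.95 / max(abs(direction))),
                         tol = 1e-12)$root
    cone_excitation_values(1 + t1 * direction[1], 1 + t1 * direction[2],
                           1 + t1 * direction[3])
  }
  expect_equal(unname(unclass(to_dkl(axis_stim(c(1, 1, 1), 0.9), cal))),
               c(0.9, 0, 0), tolerance = 1e-8)
  # unit pooled contrast on the L-M axis needs Weber contrasts beyond +/-1
  # (negative excitation); by linearity of the projection, pooled contrast
  # c on-axis must map to coordinate c, tested at c = 0.5
  expect_equal(unname(unclass(to_dkl(axis_stim(c(1, -1, 0), 0.5), cal))),
               c(0, 0.5, 0), tolerance = 1e-8)
  expect_equal(unname(unclass(to_dkl(axis_stim(c(0, 0, 1), 0.5), cal))),
               c(0, 0, 0.5), tolerance = 1e-8)

  # background scale invariance: contrasts held fixed, coordinates unchanged
  cc <- c(0.2, -0.1, 0.4)
  for (scale in c(0.5, 3)) {
    b2 <- cone_excitation_values(scale, scale, scale)
    s2 <- cone_excitation_values(scale * (1 + cc[1]), scale * (1 + cc[2]),
                                 scale * (1 + cc[3]))
    expect_equal(unclass(to_dkl(s2, dkl_calibration(b2))),
                 unclass(to_dkl(cone_excitation_values(1 + cc[1], 1 + cc[2],
                                                       1 + cc[3]), cal)),
                 tolerance = 1e-12)
  }
  expect_error(dkl_calibration(cone_excitation_values(0, 1, 1)), "positive")
})

test_that("axis purity: an S-only stimulus is pure on the s axis", {
  cal <- dkl_calibration(cone_excitation_values(2, 1.5, 0.8))
  d <- to_dkl(cone_excitation_values(2, 1.5, 1.1), cal)
  expect_lt(abs(d[["lum"]]), 1e-8)
  expect_lt(abs(d[["lm"]]), 1e-8)
  expect_gt(abs(d[["s"]]), 0.1)
  expect_error(to_dkl(cone_excitation_values(2, 1.5, 0.8),
                      list(background = cone_excitation_values(0, 1, 1))),
               "positive")
})

test_that("pooled cone contrast is the RMS of Weber contrasts", {
  bg <- cone_excitation_values(1, 2, 4)
  expect_equal(pooled_cone_contrast(bg, bg), 0)
  s <- cone_excitation_values(1.1, 2.2, 4.4)   # contrasts (0.1, 0.1, 0.1)
  expect_equal(pooled_cone_contrast(s, bg), 0.1)
  s2 <- cone_excitation_values(1.3, 2, 4)      # contrasts (0.3, 0, 0)
  expect_equal(pooled_cone_contrast(s2, bg), 0.3 / sqrt(3))
  expect_error(pooled_cone_contrast(s, cone_excitation_values(1, 0, 4)),
               "positive")
})

test_that("equiluminant ellipse: in gamut, equal arc spacing, opponent pairs", {
  cal <- fixture_calibration()
  mon <- fixture_monitor()
  st <- sample_equiluminant_ellipse(cal, mon, 8)
  expect_equal(nrow(st), 8)
  expect_equal(st$lum, rep(0, 8))
  guns <- attr(st, "gun_values")
  expect_true(all(guns >= 0 & guns <= 1))

  # arc-length oracle: dense polyline integration between consecutive points
  a <- max(abs(st$lm)); b <- max(abs(st$s))
  th <- atan2(st$s / b, st$lm / a)
  arc_between <- function(t1, t2) {
    if (t2 < t1) t2 <- t2 + 2 * pi
    tt <- seq(t1, t2, length.out = 2000)
    sum(sqrt((a * sin(tt))^2 + (b * cos(tt))^2)[-1] * diff(tt))
  }
  d <- vapply(1:8, function(i) arc_between(th[i], th[i %% 8 + 1]), numeric(1))
  expect_lt((max(d) - min(d)) / mean(d), 0.01)

  # antipodal pairs sum to the origin
  for (i in 1:4)
    expect_equal(unlist(st[i, ]) + unlist(st[i + 4, ]),
                 c(lum = 0, lm = 0, s = 0), tolerance = 1e-6)
})

test_that("gun inversion round-trips and flags out-of-gamut requests", {
  cal <- fixture_calibration()
  mon <- fixture_monitor()
  bg_guns <- dkl_to_gun_values(dkl_coords(0, 0, 0), cal, mon)
  expect_equal(unname(bg_guns), mon$background_guns, tolerance = 1e-9)

  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    g <- runif(3, 0.05, 0.95)
    lms <- as.numeric(mon$K %*% g)
    d0 <- to_dkl(cone_excitation_values(lms[1], lms[2], lms[3]), cal)
    g2 <- dkl_to_gun_values(d0, cal, mon)
    mix <- Reduce(`+`, Map(function(p, w) w * p$radiance, mon$primaries, g2))
    d1 <- to_dkl(cone_excitation(spd(mon$fundamentals$wavelengths_nm, mix),
                                 mon$fundamentals), cal)
    worst <- max(worst, max(abs(unclass(d1) - unclass(d0))))
  }
  expect_lt(worst, 1e-6)
  expect_error(dkl_to_gun_values(dkl_coords(0, 50, 0), cal, mon),
               "outside the monitor gamut")
})

test_that("packaged synthetic tables read back through the chain", {
  fpath <- system.file("extdata", "synthetic_cone_fundamentals_10deg.csv",
                       package = "visgamma")
  fund <- read_cone_fundamentals(fpath)
  expect_s3_class(fund, "cone_fundamentals")
  expect_equal(range(fund$wavelengths_nm), c(390, 830))

  spath <- system.file("extdata", "synthetic_stimulus_coordinates.csv",
                       package = "visgamma")
  st <- utils::read.csv(spath)
  expect_equal(nrow(st), 8)
  expect_true(all(abs(st$lum) < 1e-9))
  # the eight stimuli lie on an axis-aligned ellipse at equal arc spacing:
  # cardinal stimuli sit on the axes, antipodal labels are opponents
  expect_lt(abs(st$lm[st$label == "blue"]), 1e-9)
  expect_lt(abs(st$s[st$label == "red"]), 1e-9)
  expect_equal(st$s[st$label == "blue"], -st$s[st$label == "yellow"],
               tolerance = 1e-9)
  expect_equal(st$lm[st$label == "red"], -st$lm[st$label == "green"],
               tolerance = 1e-9)
  # pooled contrast column is consistent with the Weber contrast columns
  expect_equal(st$pooled,
               sqrt((st$contrast_L^2 + st$contrast_M^2 + st$contrast_S^2) / 3),
               tolerance = 1e-9)
})
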