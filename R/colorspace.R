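# DKL cone-contrast stimulus calibration.
#
# The coordinate chain is: display emission spectrum -> L/M/S cone excitation
# (integration against cone fundamentals) -> Weber cone contrasts against the
# adaptation background -> opponent DKL axes (L+M, L-M, S-(L+M)), each axis
# scaled so that an on-axis stimulus of unit pooled cone contrast receives
# coordinate 1.

#' Spectral power distribution
#'
#' A measured (or synthetic) emission spectrum: radiance per wavelength in
#' arbitrary radiometric units.
#'
#' @param wavelengths_nm strictly increasing wavelength grid in nm.
#' @param radiance non-negative radiance values, one per wavelength.
#' @return an object of class `"spd"`.
#' @export
spd <- function(wavelengths_nm, radiance) {
  if (length(wavelengths_nm) != length(radiance))
    stopf("wavelength and radiance vectors must have equal length")
  if (length(wavelengths_nm) < 2L)
    stopf("an SPD needs at least two wavelength samples")
  if (any(diff(wavelengths_nm) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (any(!is.finite(radiance)) || any(radiance < 0))
    stopf("radiance must be finite and non-negative")
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 radiance = as.numeric(radiance)),
            class = "spd")
}

#' Cone fundamentals
#'
#' Spectral sensitivity curves of the three human cone classes on a common
#' wavelength grid. Each curve must be non-negative with a single global
#' maximum, and the grid must cover at least 400-700 nm.
#'
#' @param wavelengths_nm strictly increasing wavelength grid in nm.
#' @param L,M,S sensitivity of the long-, middle- and short-wavelength cone
#'   class per wavelength (unitless).
#' @return an object of class `"cone_fundamentals"`.
#' @export
cone_fundamentals <- function(wavelengths_nm, L, M, S) {
  n <- length(wavelengths_nm)
  if (any(lengths(list(L, M, S)) != n))
    stopf("all sensitivity curves must match the wavelength grid length")
  if (any(diff(wavelengths_nm) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (min(wavelengths_nm) > 400 || max(wavelengths_nm) < 700)
    stopf("fundamentals must cover at least 400-700 nm")
  for (curve in list(L = L, M = M, S = S)) {
    if (any(curve < 0)) stopf("cone sensitivities must be non-negative")
    if (sum(curve == max(curve)) != 1L)
      stopf("each cone sensitivity curve must have a single global maximum")
  }
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 L = as.numeric(L), M = as.numeric(M), S = as.numeric(S)),
            class = "cone_fundamentals")
}

#' Synthetic log-Gaussian cone fundamentals
#'
#' A smooth stand-in for tabulated human cone fundamentals: each cone class is
#' modelled as a Gaussian in log-wavelength, peaking at 570 (L), 543 (M) and
#' 442 nm (S). The curves are synthetic; they reproduce the qualitative
#' ordering and overlap of human cone sensitivities, not any individual
#' observer. Useful wherever the calibration chain is exercised without a
#' measured fundamentals table.
#'
#' @param wavelengths_nm wavelength grid (default 390-830 nm at 1 nm).
#' @return a [cone_fundamentals()] object.
#' @export
synthetic_cone_fundamentals <- function(wavelengths_nm = 390:830) {
  shape <- function(peak, sigma_log)
    exp(-(log(wavelengths_nm / peak))^2 / (2 * sigma_log^2))
  cone_fundamentals(wavelengths_nm,
                    L = shape(570, 0.080),
                    M = shape(543, 0.075),
                    S = shape(442, 0.060))
}

#' Synthetic display monitor
#'
#' Three Gaussian-shaped primaries (red, green, blue guns) on the fundamentals
#' grid, loosely emulating a DLP projector gamut. Gun intensities combine
#' linearly; no gamma correction is modelled.
#'
#' @param fundamentals a [cone_fundamentals()] object used for excitation
#'   computations with this monitor.
#' @param background_guns gun values of the neutral background, in `[0, 1]`.
#' @return an object of class `"monitor"` with elements `primaries` (list of
#'   three [spd()]s), `fundamentals`, `background_guns`, and the derived 3x3
#'   cone matrix `K` (columns: excitation of each full-intensity gun).
#' @export
synthetic_monitor <- function(fundamentals = synthetic_cone_fundamentals(),
                              background_guns = c(0.5, 0.5, 0.5)) {
  wl <- fundamentals$wavelengths_nm
  gun <- function(peak, sd) spd(wl, exp(-(wl - peak)^2 / (2 * sd^2)))
  monitor(list(R = gun(610, 24), G = gun(545, 28), B = gun(465, 22)),
          fundamentals, background_guns)
}

#' Monitor from measured primaries
#'
#' @param primaries list of three [spd()] objects (full-intensity gun spectra).
#' @param fundamentals a [cone_fundamentals()] object.
#' @param background_guns gun values of the neutral background, in `[0, 1]`.
#' @return an object of class `"monitor"`; see [synthetic_monitor()].
#' @export
monitor <- function(primaries, fundamentals, background_guns = c(0.5, 0.5, 0.5)) {
  if (length(primaries) != 3L) stopf("a monitor needs exactly three primaries")
  if (any(background_guns < 0) || any(background_guns > 1))
    stopf("background gun values must lie in [0, 1]")
  K <- vapply(primaries, function(p) unclass(cone_excitation(p, fundamentals)),
              numeric(3))
  if (abs(det(K)) < 1e-12 * prod(pmax(colSums(abs(K)), .Machine$double.eps)))
    stopf("monitor primaries are linearly dependent in cone space")
  structure(list(primaries = primaries, fundamentals = fundamentals,
                 background_guns = as.numeric(background_guns), K = K),
            class = "monitor")
}

#' Cone excitation of an emission spectrum
#'
#' Trapezoidal integral of radiance times cone sensitivity over wavelength,
#' per cone class. The SPD is linearly interpolated onto the fundamentals grid
#' (radiance zero outside its own support), so the result is linear in
#' radiance.
#'
#' @param x an [spd()] object.
#' @param fundamentals a [cone_fundamentals()] object.
#' @return an object of class `"cone_excitation"`: named numeric `(L, M, S)`.
#' @export
cone_excitation <- function(x, fundamentals) {
  if (!inherits(x, "spd")) x <- do.call(spd, unname(x[1:2]))
  wl <- fundamentals$wavelengths_nm
  lo <- max(min(wl), min(x$wavelengths_nm))
  hi <- min(max(wl), max(x$wavelengths_nm))
  if (lo >= hi)
    stopf("SPD wavelength range [%g, %g] does not overlap the fundamentals grid",
          min(x$wavelengths_nm), max(x$wavelengths_nm))
  grid <- wl[wl >= lo & wl <= hi]
  rad <- stats::approx(x$wavelengths_nm, x$radiance, xout = grid,
                       yleft = 0, yright = 0)$y
  trap <- function(sens) {
    s <- stats::approx(wl, sens, xout = grid)$y * rad
    sum(diff(grid) * (s[-1] + s[-length(s)]) / 2)
  }
  cone_excitation_values(trap(fundamentals$L), trap(fundamentals$M),
                         trap(fundamentals$S))
}

#' Construct cone excitation values directly
#'
#' @param L,M,S non-negative excitation of each cone class.
#' @return an object of class `"cone_excitation"`.
#' @export
cone_excitation_values <- function(L, M, S) {
  v <- c(L = L, M = M, S = S)
  if (any(!is.finite(v)) || any(v < 0))
    stopf("cone excitations must be finite and non-negative")
  structure(v, class = "cone_excitation")
}

#' Pooled cone contrast
#'
#' Root-mean-square of the three Weber cone contrasts of a stimulus against
#' the adaptation background: `sqrt(mean(c(dL/L, dM/M, dS/S)^2))`. Equal
#' contrast `c` on all three cone classes pools to `c`.
#'
#' @param stimulus,background `"cone_excitation"` objects; all background
#'   components must be strictly positive.
#' @return a non-negative scalar; zero iff stimulus equals background.
#' @export
pooled_cone_contrast <- function(stimulus, background) {
  cc <- weber_contrasts(stimulus, background)
  sqrt(mean(cc^2))
}

weber_contrasts <- function(stimulus, background) {
  s <- unclass(stimulus); b <- unclass(background)
  if (any(b <= 0)) stopf("background cone excitations must be strictly positive")
  if (any(s < 0)) stopf("stimulus cone excitations must be non-negative")
  (s - b) / b
}

#' DKL calibration for a background
#'
#' Computes the three axis normalization constants `k_lum`, `k_lm`, `k_s`
#' such that a stimulus lying exactly on one cardinal DKL axis with pooled
#' cone contrast 1 receives coordinate 1 on that axis (and 0 on the others).
#' With the opponent projection used here (see [to_dkl()]) the constants are
#' background-independent in contrast space:
#' the on-axis unit-pooled-contrast stimuli have Weber contrasts
#' `(1, 1, 1)` (luminance), `sqrt(3/2) * (1, -1, 0)` (L-M) and
#' `sqrt(3) * (0, 0, 1)` (S-(L+M)), giving `k_lum = 1/2`,
#' `k_lm = 1/sqrt(6)` and `k_s = 1/sqrt(3)`.
#'
#' @param background a `"cone_excitation"` object with strictly positive
#'   components.
#' @return an object of class `"dkl_calibration"` with fields `background`,
#'   `k_lum`, `k_lm`, `k_s`.
#' @export
dkl_calibration <- function(background) {
  b <- unclass(background)
  if (any(!is.finite(b)) || any(b <= 0))
    stopf("background cone excitations must be strictly positive")
  structure(list(background = background,
                 k_lum = 1 / 2,
                 k_lm = 1 / sqrt(6),
                 k_s = 1 / sqrt(3)),
            class = "dkl_calibration")
}

#' Project cone excitations to DKL coordinates
#'
#' Background-relative opponent projection. With Weber contrasts
#' `cl = dL/L_bg`, `cm = dM/M_bg`, `cs = dS/S_bg`:
#' `lum = k_lum * (cl + cm)`, `lm = k_lm * (cl - cm)`,
#' `s = k_s * (cs - (cl + cm)/2)`. The background maps to the origin, and a
#' stimulus differing from background only in S-cone excitation is pure on
#' the `s` axis.
#'
#' @param stimulus a `"cone_excitation"` object.
#' @param cal a [dkl_calibration()] object.
#' @return an object of class `"dkl"`: named numeric `(lum, lm, s)`.
#' @export
to_dkl <- function(stimulus, cal) {
  cc <- weber_contrasts(stimulus, cal$background)
  dkl_coords(lum = cal$k_lum * (cc[1] + cc[2]),
             lm  = cal$k_lm  * (cc[1] - cc[2]),
             s   = cal$k_s   * (cc[3] - (cc[1] + cc[2]) / 2))
}

#' @rdname to_dkl
#' @param lum,lm,s coordinate values on the three DKL axes.
#' @export
dkl_coords <- function(lum, lm, s) {
  v <- c(lum = unname(lum), lm = unname(lm), s = unname(s))
  if (any(!is.finite(v))) stopf("DKL coordinates must be finite")
  structure(v, class = "dkl")
}

# inverse of to_dkl in contrast space
dkl_to_contrasts <- function(dkl, cal) {
  a <- dkl[["lum"]] / cal$k_lum      # cl + cm
  b <- dkl[["lm"]] / cal$k_lm        # cl - cm
  cs <- dkl[["s"]] / cal$k_s + a / 2
  c((a + b) / 2, (a - b) / 2, cs)
}

#' Gun values realizing a DKL coordinate
#'
#' Inverts the calibration chain: DKL coordinates -> cone contrasts -> cone
#' excitations -> linear mixture of the monitor primaries. Errors if the
#' requested color lies outside the monitor gamut, naming the offending gun.
#'
#' @param dkl a [dkl_coords()] object.
#' @param cal a [dkl_calibration()] object; its background must equal the cone
#'   excitation of the monitor's background gun values.
#' @param mon a [monitor()] object.
#' @param tol numerical tolerance for the gamut check.
#' @return numeric gun intensities `(R, G, B)` in `[0, 1]`.
#' @export
dkl_to_gun_values <- function(dkl, cal, mon, tol = 1e-9) {
  cc <- dkl_to_contrasts(dkl, cal)
  lms <- unclass(cal$background) * (1 + cc)
  g <- solve(mon$K, lms)
  bad <- which(g < -tol | g > 1 + tol)
  if (length(bad))
    stopf("requested color is outside the monitor gamut: gun %s = %.4f",
          paste(names(mon$primaries)[bad], collapse = ","), g[bad[1]])
  stats::setNames(pmin(pmax(g, 0), 1), names(mon$primaries))
}

# largest t such that t * dkl_direction stays inside the gamut (lum fixed)
gamut_radius <- function(direction, cal, mon) {
  g0 <- solve(mon$K, unclass(cal$background))
  g1 <- solve(mon$K, unclass(cal$background) *
                (1 + dkl_to_contrasts(direction, cal)))
  v <- g1 - g0
  lim <- ifelse(v > 0, (1 - g0) / v, ifelse(v < 0, -g0 / v, Inf))
  min(lim)
}

#' Sample equiluminant stimuli along a gamut-filling ellipse
#'
#' Returns `n` chromatic stimuli on the DKL equiluminance plane (`lum = 0`)
#' of the calibration background, lying on an ellipse whose axes are aligned
#' with the `lm` and `s` cardinal axes. Each semi-axis spans 95% of the
#' monitor gamut along that axis, shrunk further (uniformly) if intermediate
#' angles would leave the gamut. Points are spaced at equal arc-length
#' distances along the ellipse, starting on the positive `lm` axis, so for
#' even `n` antipodal sample pairs are exact color opponents.
#'
#' @param cal a [dkl_calibration()] object for the monitor background.
#' @param mon a [monitor()] object defining the gamut.
#' @param n number of stimuli (at least 3).
#' @param fill fraction of the gamut radius to use per axis (default 0.95).
#' @return a data.frame with columns `lum`, `lm`, `s` and attribute
#'   `"gun_values"` (n x 3 matrix).
#' @export
sample_equiluminant_ellipse <- function(cal, mon, n, fill = 0.95) {
  if (n < 3) stopf("need at least 3 stimuli on the ellipse")
  bg_guns <- solve(mon$K, unclass(cal$background))
  if (any(bg_guns < 0) || any(bg_guns > 1))
    stopf("calibration background lies outside the monitor gamut")
  a <- fill * gamut_radius(dkl_coords(0, 1, 0), cal, mon)
  b <- fill * gamut_radius(dkl_coords(0, 0, 1), cal, mon)
  # uniform shrink if the ellipse pokes out of the (convex) gamut section
  th_dense <- seq(0, 2 * pi, length.out = 721)[-721]
  shrink <- 1
  for (th in th_dense) {
    r_ell <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
    if (r_ell == 0) next
    r_gam <- gamut_radius(dkl_coords(0, a * cos(th) / r_ell, b * sin(th) / r_ell),
                          cal, mon)
    shrink <- min(shrink, fill * r_gam / r_ell)
  }
  a <- a * shrink; b <- b * shrink
  # equal arc-length spacing via dense cumulative arc length
  tt <- seq(0, 2 * pi, length.out = 20001)
  dx <- -a * sin(tt); dy <- b * cos(tt)
  sp <- sqrt(dx^2 + dy^2)
  arc <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tt)))
  total <- arc[length(arc)]
  targets <- (seq_len(n) - 1) / n * total
  t_at <- stats::approx(arc, tt, xout = targets)$y
  pts <- data.frame(lum = rep(0, n), lm = a * cos(t_at), s = b * sin(t_at))
  guns <- t(vapply(seq_len(n), function(i)
    dkl_to_gun_values(dkl_coords(0, pts$lm[i], pts$s[i]), cal, mon),
    numeric(3)))
  attr(pts, "gun_values") <- guns
  pts
}

#' Read an SPD or cone-fundamentals table
#'
#' Delimited text with a header row: `wavelength_nm, value` for an SPD;
#' `wavelength_nm, L, M, S` for fundamentals.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return an [spd()] or [cone_fundamentals()] object.
#' @export
read_spd <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  spd(d[[1]], d[[2]])
}

#' @rdname read_spd
#' @export
read_cone_fundamentals <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  cone_fundamentals(d[[1]], d[[2]], d[[3]], d[[4]])
}

#' Write a stimulus coordinate table
#'
#' One row per stimulus: label, DKL triple, Weber cone contrasts and pooled
#' cone contrast, as delimited text.
#'
#' @param stimuli data.frame as returned by [sample_equiluminant_ellipse()].
#' @param labels character vector of stimulus labels.
#' @param cal a [dkl_calibration()] object.
#' @param path output file path.
#' @export
write_stimulus_table <- function(stimuli, labels, cal, path) {
  rows <- lapply(seq_len(nrow(stimuli)), function(i) {
    cc <- dkl_to_contrasts(dkl_coords(stimuli$lum[i], stimuli$lm[i],
                                      stimuli$s[i]), cal)
    data.frame(label = labels[i], lum = stimuli$lum[i], lm = stimuli$lm[i],
               s = stimuli$s[i], contrast_L = cc[1], contrast_M = cc[2],
               contrast_S = cc[3], pooled = sqrt(mean(cc^2)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
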