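---
title: "Methods: simulating and analyzing color-induced visual gamma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing color-induced visual gamma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Homogeneous color disks induce narrowband gamma oscillations (~30-100 Hz) in
early visual cortex. Whether some hues (famously red) induce *intrinsically*
stronger gamma than others can only be decided if the stimuli drive the
LGN - and hence V1's input - equally. `visgamma` implements the full
computational chain of such a study: stimuli equated in DKL cone-contrast
coordinates, source-level (virtual-dipole) MEG trials, multitaper
baseline-normalized power-change spectra, a constrained spectral peak model
selected by adjusted R-squared, early ERF (N70) features, a QUEST adaptive
staircase for the behavioral task, and the group-statistics layer.

Because real MEG recordings are out of scope, the package ships a synthetic
virtual-dipole generator whose *defaults are the group-level effect sizes the
analysis is expected to recover*: a `run_study()` call is therefore a
closed-loop parameter-recovery experiment that validates every stage of the
analysis against known ground truth.

# Stimulus calibration in DKL space

Cone excitations are trapezoidal integrals of display emission spectra
against cone fundamentals. Coordinates are background-relative Weber
contrasts `cl, cm, cs` projected on opponent axes:

* luminance `lum = k_lum (cl + cm)`,
* red-green `lm = k_lm (cl - cm)`,
* S-opponent `s = k_s (cs - (cl + cm)/2)`.

The `-(cl+cm)/2` term removes the luminance component from the S axis so a
pure luminance modulation has `s = 0`. Pooled cone contrast is the RMS of
the three Weber contrasts (equal contrast `c` on all cones pools to `c`);
with that convention the normalization constants demanded by
"unit pooled contrast on-axis maps to unit coordinate" are closed-form and
background-independent: `k_lum = 1/2`, `k_lm = 1/sqrt(6)`,
`k_s = 1/sqrt(3)`. `dkl_calibration()` returns them; the test suite verifies
the property by root-finding rather than reusing the formula.

Equiluminant stimulus sets are sampled from an ellipse in the `(lm, s)`
plane, axes aligned with the cardinal axes, each semi-axis at 95% of the
monitor gamut along that axis (uniformly shrunk if an oblique direction
would leave the gamut), with points at equal *arc-length* spacing. For even
`n` the antipodal pairs are then exact color opponents and the four cardinal
stimuli fall exactly on the axes.

Tabulated human cone fundamentals are not bundled; the package generates
log-Gaussian pseudo-fundamentals (peaks 570/543/442 nm) and a Gaussian
three-primary monitor, both clearly labelled synthetic. They reproduce the
qualitative overlap structure of human cones, which is all the calibration
chain's correctness properties need; any measured fundamentals/primaries
table can be supplied through `read_cone_fundamentals()`/`read_spd()`.

# The synthetic virtual-dipole generator

Each trial spans -1.2 to +1.4 s around stimulus onset at 1200 Hz. Per
dipole it contains:

* **1/f background noise**, synthesized by spectral shaping
  (`f^(-exponent/2)` amplitude, exponent 1 by default - a typical MEG
  background slope in the gamma range);
* **induced gamma**: a constant-amplitude sinusoid from onset onward at the
  condition's peak frequency plus a per-participant offset. Phases are
  drawn per trial as a randomly rotated, randomly permuted *balanced* set:
  marginally uniform (so the rhythm is induced, not phase-locked, and
  appears only in power), yet summing to zero across a block's trials so
  trial-averaged ERFs contain no gamma residue even at small trial counts;
* an optional **second high-gamma sinusoid** whose frequency offset is
  drawn independently of the first - the two fitted peaks are therefore
  uncorrelated across the cohort, which the suite checks (`|r| < 0.15`);
* an **N70-like deflection**: a difference-of-Gaussians (widths 8/20 ms,
  surround weight 0.35) with its single minimum at the condition's latency,
  multiplied by the dipole's random +/-1 polarity. The surround weight is
  chosen so the deflection, not its flanking positivity, dominates the
  55-95 ms polarity-flip window at every registry latency.

**Amplitude calibration.** Injected magnitudes are calibrated *through the
analysis pipeline itself*: the expected multitaper noise power per 1-Hz bin
(Monte-Carlo with a fixed internal seed, cached) and the deterministic
per-bin power of a unit sinusoid under the taper scheme give the amplitude
whose expected percent power change equals the registry target.
Two calibration modes exist because a narrowband peak cannot
simultaneously produce the same percent change at its peak *bin* and as a
*band* average (peak +/- 10 Hz): `"bin"` matches the single-bin change
(verified by Monte Carlo within 10%); the generator uses `"band"`, since
the band average is the study-level summary measure the recovery targets
are stated in. N70 amplitudes are calibrated analogously via the filtered
template's window mean and the mean reciprocal baseline SD (z-scoring
divides by each trial's own baseline SD, so Jensen's inequality matters at
this noise level).

**Cohort structure.** Between-participant variability: gamma-frequency
offsets (population SD 8 Hz; independent SD 5 Hz for the second peak) and a
log-normal power gain (sigma 0.3). Offsets are randomly permuted Gaussian
quantiles and gains are normalized to cohort mean 1 - a balanced-sampling
design choice so that even 10-participant cohorts are centered on the
population values instead of inheriting a +/-2.5 Hz cohort-mean wobble.
The per-condition trial count (30), cohort sizes, staircase target (85%),
and all condition-level effect sizes are registry defaults
(`condition_registry()`); the four off-axis hues, which lack cardinal-axis
anchors, use interpolated defaults chosen once: 22% gamma for the
lime-magenta diagonal (green-yellow, red-blue), 14% for orange-cyan, making
the eight-color average exactly 19.0% with the lime-magenta diagonal
responding more strongly than orange-cyan. Behavioral change times follow a truncated Cauchy
(x0 = 1.65 s, FWHM = 0.2 s, support [0.3, 2] s); trials with changes before
1.3 s are excluded from spectral analysis, mirroring the behavioral paradigm's
trial-rejection rule (the ERF path keeps all trials - its window ends at 0.6 s, before
any change can occur).

**Dipole count.** The study default is 106 dipoles per participant, the
size of a subsampled cortical-atlas V1 patch - the scale at which
source-level studies average full spectra. This is not cosmetic: averaging ~3000 independent
segment-sets per condition is what brings per-bin change-spectrum noise to
~0.9 percentage points, below the 5% minimum-amplitude bound of the peak
model - the property that makes model selection specific on peak-free
spectra. Materialized datasets (`generate_dataset()`) default to 1 dipole;
`run_study()` streams one participant at a time so the study-scale dipole
count never holds more than ~80 MB of samples.

# Spectral analysis

Baseline (-1.0-0 s) and stimulus (0.3-1.3 s) periods are cut into 50%
overlapping epochs: 500 ms (single Hann taper) for frequencies up to
20 Hz, 333 ms with 3 Slepian tapers above. The design brief of "three tapers, +/-3 Hz smoothing" is internally
inconsistent for a 333-ms window
(NW = T x 3 Hz = 1, for which only ~one taper is well concentrated); the
taper *count* wins, and the effective smoothing - somewhat wider and softer
than an NW = 2 design - is whatever the three NW = 1 Slepians deliver. All
tapers carry unit energy and power is *averaged* (not summed) over tapers,
so white noise of variance v has flat expected power v (checked to 2%).
Epochs are zero-padded to 1 s (1-Hz grid); percent change is computed per
bin against the per-condition average baseline spectrum. The
time-frequency variant centers epochs on every 12th sample (100 Hz output;
a config switch restores the full rate) with 4-s padding (0.25-Hz grid).

# The peak model

Trial-averaged change spectra over 15-120 Hz are fitted with (1) a line,
(2) line + one Gaussian, (3) line + two Gaussians; Gaussian amplitudes
are bounded below at 5%, SDs in [1.5, 10] Hz, the first mean above 21 Hz,
the second above 61 Hz, all means below 120 Hz (the grid edge). Fits are
bounded weighted least squares (Levenberg-Marquardt) from 8 deterministic
starts per candidate (largest local maxima of the 5-bin-smoothed spectrum,
two SD seeds). Bin weights default to `max(change, 0.01)/max(change)` -
"scaled power change" read as min-max scaling, so stronger responses count
more; `uniform` and `softmax` alternatives sit behind a config switch.
Adjusted R-squared uses the weighted sum of squares with n = 106 bins and
p = 2/5/8; the largest value wins and near-ties (< 1e-9) go to the simpler
model. A fitted Gaussian below 61 Hz counts as the low (first) gamma peak;
conditions without a low peak inherit the participant's mean low-peak
frequency for band extraction but are flagged and excluded from analyses
that report frequencies.

Specificity and sensitivity are assessed on 500 spectra at the study's
noise level. Because one exact null spectrum costs ~3000 simulated
segment-sets, the suite draws them from a Gaussian ensemble matched to the
empirical per-segment-set mean and covariance of the pipeline's change
contributions - exact to O(K^-1/2) with K ~ 3000 - and separately verifies
that ensemble against 20 exact pipeline spectra at a small dipole count.
Measured rates at the defaults: ~2% false peaks on null spectra (well
inside both the 10% bound and its 95%-specificity restatement) and 100%
detection of 20%-amplitude, 4-Hz-SD peaks.

# ERF processing

An acausal Gaussian kernel with amplitude response
`|H(f)| = exp(-2 pi^2 sigma^2 f^2)` and -6 dB (amplitude 0.5) at 80 Hz
gives `sigma = sqrt(ln 2 / 2) / (80 pi)` (~2.34 ms), truncated at 4 sigma
with reflection padding. Traces are z-scored against the -1.0-0 s per-trial
baseline (the spectral baseline window; configurable to -0.2-0 s), cut to
-0.2-0.6 s, sign-flipped per dipole (one sign for all conditions, from the
all-condition average's 55-95 ms mean) and averaged. N70 peak time is the
50-110 ms minimum of the condition-average trace, slope the OLS line over
2-12 ms pre-peak on that average, and per-trial amplitude the mean over
peak +/- 10 ms.

# QUEST

The staircase is a grid Bayes filter in log10 contrast (200 points over
[-3, 0], Gaussian prior mean -0.7, SD 0.5) for the threshold of a Weibull
psychometric (beta = 3.5, guess 0.5, lapse 0.01) - the method's canonical defaults. Placement
is the posterior-mean estimate of the 85%-correct contrast; the study-level
threshold read-out is the mean of the last ten presented intensities. The
simulated observer uses the same Weibull family parameterized by its 85%
point, so staircase accuracy converges to ~85-86% (the small upward bias is
the usual consequence of adaptive placement under a lapse-bounded ceiling).

# Statistics

One-way repeated-measures ANOVA with Greenhouse-Geisser epsilon from the
double-centered condition covariance; Holm step-down pairwise paired
t-tests; JZS Bayes factors (Cauchy prior scale 1) by adaptive quadrature,
cross-checked against a 200k-point trapezoid oracle and reproducing
BF01 = 7.0 at t = 0.135, n = 30; percentile bootstrap CIs; t-max
familywise correction of correlation courses using per-participant sign
flips (exhaustively enumerated when 2^n fits the permutation budget), with
a Fisher-z transform before the group t test (a variance-stabilizing
choice; a switch averages raw r instead); and per-participant OLS residualization of gamma power on N70
slope and amplitude.

# Problem sizes and runtimes

The reference recovery run is 10 participants x 30 trials x 9 conditions
x 106 dipoles (about 7-9 minutes on one CPU); the test suite runs it once
and shares it across recovery checks. Property simulations use 500
surrogate spectra, 500 t-max/bootstrap replicates, and 20-run staircase
batches - sizes chosen to keep the whole suite within a desktop coffee
break while leaving binomial slack around every rate bound.

# What passing does and does not show

The generator produces stationary 1/f noise, constant-amplitude
sinusoidal gamma and a deterministic evoked template. Real MEG gamma is
burst-like with amplitude-frequency comodulation; real backgrounds are
nonstationary with line noise, eye/muscle artifacts and head movement;
real evoked fields vary in shape across trials. Passing recovery therefore
certifies the *analysis chain* - calibration, spectral estimation, model
selection, feature extraction, statistics - not the realism of any of
those physiological complications, which sit outside this package's scope
(as do beamforming, atlas registration and artifact rejection).
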