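---
title: "Models and methods behind undulokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind undulokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`undulokin` turns coordinates digitized from orthogonal high-speed video
of a steadily swimming elongate fish into per-trial kinematic variables
and a cross-speed statistical comparison.  This vignette records the
models, the estimators, the tunable parameters, and the design choices
made where the problem left the design genuinely open — in enough detail
that a user can judge what the package's passing tests do and do not
demonstrate.

## The measurement model

One *trial* is one animal swimming at one imposed flow speed.  Its raw
material is

* a **midline sequence**: per video frame, 200 points along the dorsal
  body midline, ordered snout to tail tip and equally spaced in arc
  length, in calibrated length units;
* **landmark tracks**: lateral-view (x, z) positions of the snout tip,
  pectoral fin insertion, pectoral fin tip and pelvic fin insertion
  (landmarks 1–4), and dorsal-view (x, y) positions of landmarks 2–4;
* **metadata**: individual, body length BL, flow speed in BL s⁻¹, water
  kinematic viscosity ν (default 10⁻⁶ m² s⁻¹).

Coordinate conventions: x streamwise (toward the tail at rest), y
lateral (dorsal view), z vertical (lateral view, positive up); the
midline origin is at the snout per frame.  The two views share the x
axis, so a landmark seen in both merges to
(mean of the two x's, dorsal y, lateral z); frames whose x's disagree by
more than 2% of BL (configurable) are flagged and excluded rather than
averaged.  Missing detections stay masked — they are never interpolated,
to avoid manufacturing kinematics where the tracker failed.

## Per-trial estimators

**Cycle detection.**  All variables are evaluated over the first complete
tail beat.  The tail-tip trace is detrended and low-pass filtered with a
zero-phase moving average (window `fps / (10 · f)` frames, with `f` first
estimated from the dominant Fourier component).  Zero crossings are
located with sub-frame precision by linear interpolation; consecutive
crossings alternate direction, so crossings *i* and *i + 2* bound exactly
one oscillation.  Detrending is done in two passes: same-direction
crossings of a sine shift equally under a constant offset, so a
mean-centred first pass gives an unbiased period estimate even over a
non-integer number of cycles; a line fitted jointly with a sinusoid at
that frequency then removes drift without the partial-cycle bias a plain
least-squares line would introduce.  Tail beat frequency is the
reciprocal of the crossing-to-crossing period, and tail amplitude is the
peak-to-peak tip excursion inside the window, reported in BL.

**Traveling wave.**  Each of the 200 stations contributes the phase of
the discrete Fourier component of its lateral displacement at the tail
beat frequency, over one cycle of frames.  For a head-to-tail wave of
wavelength λ (BL), phase falls linearly along the body with slope
−2π/λ.  The slope is fit by least squares over the posterior half of the
body excluding the final 5% (where tip digitizing noise concentrates);
stations with less than 1% of the tip's oscillation power are excluded;
the phase is unwrapped from the tail (cleanest signal) toward the head.
Then `c = 2π·TBF/|slope|` and `λ = c/TBF` — the two are a single
estimate by construction, so `c = λ·TBF` holds to numerical precision.
A positive slope (tail-to-head propagation) or a slope magnitude below
0.5 rad/BL (standing wave) is an error, not a number.  The
single-frequency phase gradient was chosen over zero-crossing tracking
because it uses every frame of the single analysed cycle and degrades
gracefully under noise; the fit region and power threshold are
configurable.

**Curvature.**  Each frame's midline is smoothed with a Savitzky–Golay
filter (default window 15 of 200 stations, order 3) and the planar
curvature `κ = |x′y″ − y′x″|/(x′² + y′²)^{3/2}` is evaluated by central
differences; the formula is parametrization-invariant, so equal-index
differencing is exact up to discretization.  κ is reported in BL⁻¹; the
trial's `k_max` is the maximum over stations and cycle frames and
`k_max_loc` its arc-length fraction.  On closed-form fixtures the
defaults are accurate to well under 1% (circles of radius 0.25–2 BL) and
within 2% for a sine midline's `a(2π/λ)²` peak.  The window is a
bias–variance dial: with heavy digitizing noise the default window
under-smooths second derivatives, and `k_max` should be read as
noise-sensitive (see limitations).

**Angles.**  Body angle is `atan2(z₁ − z₄, |x₁ − x₄|)` per frame,
averaged over the cycle, positive snout-up.  The angle of attack is the
elevation of the 3-D chord from the pelvic insertion to the pectoral fin
tip, `asin(Δz/‖Δ‖)`, averaged over the cycle.  The source material is
ambiguous about the sign convention of this angle; we direct the chord
anterior-minus-posterior so a snout-up posture gives a positive angle,
consistent with the body angle.  Both angles require their landmarks in
at least half of the cycle frames.

**Dimensionless numbers.**  `Re = U·BL/ν` with U in m s⁻¹;
`St = TBF·A/U`.  Fin effort is `TBF × A` (BL s⁻¹), and since the
amplitude is kept in BL and the speed in BL s⁻¹, the identity
`St = fin_effort / speed_bl` is exact in the summary table — the
Strouhal column is computed that way deliberately so the identity
survives floating point.

## The synthetic swimmer

The generator exists to give every estimator a recoverable ground truth;
it is a test harness, not a hydrodynamic model.  The dorsal-view lateral
displacement is a traveling wave with a power-law amplitude envelope,

y(u, t) = (A_pp/2) · u^p · sin(2π(u/λ − f·t) + φ₀) + ε,

with u the arc-length fraction, all lengths in BL, and ε i.i.d. Gaussian
per coordinate.  Choices made where the biology is unspecified:

* **Envelope** `u^p`, default p = 2: smooth, monotone, single-parameter,
  typical of posteriorly growing amplitude in undulatory swimmers.  The
  true envelope of any particular species is not modelled.
* **Arc-length construction**: x is integrated as
  `dx = sqrt(ds² − dy²)` on a 10× fine grid and subsampled, so the
  200-point midline has arc length exactly 1 BL and truly equal station
  spacing — the property the wave and curvature estimators assume.
* **Pitch**: the body angle tilts the rigid anterior axis in the
  lateral-view landmark geometry only; the dorsal midline is generated
  without the cos(BA) foreshortening a physically pitched body would
  show.  This keeps the midline's arc length at 1 BL and the wave
  parameters exactly recoverable; it means the generator does not test
  robustness to pitch-induced dorsal foreshortening.
* **Landmark geometry**: pectoral insertion at u = 0.25 and pelvic
  insertion at u = 0.45 along the axis (anatomical fractions are not
  published; these are plausible for a slender-bodied shark); the
  pectoral-tip chord has fixed length 0.22 BL and fixed lateral offset,
  so its prescribed pitch is recovered exactly.
* **Noise** is i.i.d. per coordinate ("digitizing jitter"), with no
  along-body or temporal correlation — the simplest falsifiable model.
  Because 200 i.i.d. draws per frame accumulate in the polyline length,
  cohort noise defaults to 0.001 BL, which keeps arc-length inflation
  (~8%) inside the container's 10% sanity bound; real midline extractors
  smooth along the body, making their effective independent jitter
  smaller than raw pixel error.  Recovery tests run at up to 0.002 BL.
* **Sampling**: specs default to 250 frames s⁻¹ and a 2.2-cycle
  duration.  The invariant is ≥ 10 samples per half-cycle; at 250 fps
  and 2–4 Hz every estimator is already within ~0.1% of its asymptote,
  so simulating a full 1000 fps camera would only scale memory and
  runtime, not accuracy.

A simulated **cohort** reproduces the repeated-measures design: 5
individuals × 11 speeds (0.5–6 BL s⁻¹) with 4 trials missing for one
individual, 51 trials.  Per-trial targets are drawn as
speed trend + individual effect + trial noise; the default trends
linearly interpolate published per-speed means of TBF, wave speed, fin
effort and body angle (`reference_speed_trends()`), so a default cohort
carries a realistic speed dependence: TBF flat below 2 BL s⁻¹ then
rising, body angle falling from ~40° to ~15°, fin effort minimal near
1 BL s⁻¹.  Between/within-individual SDs default to values of the order
of the published per-speed SDs.  The ground-truth table stores
`wave_speed = wavelength × tbf` exactly.

What passing recovery tests therefore show: the estimators invert the
generator's wave model accurately under modest i.i.d. noise and the
statistics machinery behaves on a realistic design.  What they do not
show: robustness to real digitizing artefacts (correlated jitter,
dropped frames, pitch foreshortening, non-sinusoidal waveforms,
amplitude modulation between beats).

## Cross-speed statistics

**Gate.**  Per variable, the additive individual-blocked model
`y ~ individual + speed` is fit; Levene's test (median-centred, across
speed groups) and Shapiro–Wilk are applied to its residuals.  If neither
rejects at α = 0.05 the parametric route is taken, otherwise the
aligned-rank route.  Residuals (rather than raw values) are tested
because the assumptions at stake are those of the model's error term; a
constant response routes to the rank test with a warning.

**RM-ANOVA.**  "Repeated measures" is implemented as the additive
fixed-effects block design, with the speed effect tested sequentially
after individuals.  This is the unique reading that reproduces the
design's degrees of freedom on the unbalanced table:
`df = (k − 1, N − 1 − (k − 1) − (n − 1))`, i.e. (10, 36) for 51 trials,
11 speeds, 5 individuals.  No sphericity correction is applied.  Monte
Carlo under a normal null (individual effects plus i.i.d. error, 2000
reps) puts the type-I error at the nominal 5%.

**ART-ANOVA.**  For the single within factor: the response is aligned
for speed (residuals of the full additive fit plus the estimated speed
effect), ranked with average ranks for ties, and the same blocked ANOVA
is run on the ranks.  Alignment is a linear-model operation, so the
procedure is invariant to positive affine transforms of the data but —
unlike a pure rank test — not to arbitrary monotone transforms; the test
suite asserts the affine invariance.  Under a log-normal null with
additive individual blocks the type-I error is again ~5%.  A fully tied
response is handled explicitly (F = 0, p = 1) rather than trusting
floating-point residuals of a perfect fit.

**Letters.**  All pairwise speed contrasts use the Tukey–Kramer
adjustment (studentized range at the model's residual df, valid for
unequal group sizes) via `emmeans`; the compact letter display is
computed by the insert-and-absorb algorithm and letters are assigned in
increasing speed order.  Two speeds share a letter exactly when their
adjusted contrast p-value exceeds α.  No further multiplicity correction
is layered on top.

**PCA.**  On the eight *independent* variables (angle of attack, body
angle, tail amplitude, maximum curvature and its location, Reynolds
number, tail beat frequency, wave speed) — Strouhal, fin effort and
wavelength are excluded as deterministic functions of the others.
Variables are z-scored; percent variance per axis and per-axis variable
contributions (`100 · loading²`, summing to 100 per axis) are reported.
Rows with missing variables are dropped and listed.  PC1's sign is fixed
by orienting it to correlate positively with swimming speed; other axes
keep `prcomp`'s arbitrary sign.  On default synthetic cohorts PC1 is a
speed axis with tail beat frequency, Reynolds number and wave speed
loading opposite body angle — the injected trend structure.

## Numerical and degenerate-input policy

Estimators raise informative errors instead of returning numbers when
the input cannot support the estimate: fewer than three zero crossings
(no complete cycle), a flat tip trace (range < 10⁻⁶ BL), a standing wave
or head-ward phase slope, fewer than 10 usable phase stations, duplicate
consecutive midline points, coincident landmarks, missing merged 3-D
tracks.  The pipeline wrapper converts per-trial failures into logged
skips and fails only when every trial fails.  File parsers name the
offending row; spec validators name the offending field.  All
randomness flows from explicit integer seeds, and equal seeds give
bit-identical artifacts (timestamps live only in the log and run
metadata).

## Problem sizes used in the tests

The shipped suite runs the full 51-trial design for the statistics and
acceptance checks, 50 randomized trials for parameter recovery
(noise 0.001 BL, 250 fps), 20 replicate seeds for wave-speed noise
robustness, and 2000 Monte-Carlo replicates per ANOVA null — sizes at
which the Monte-Carlo standard error of a 5% rejection rate is about
0.5 percentage points.

## Known limitations

* `k_max` under realistic noise is biased upward; treat it as a relative
  measure unless the midlines are smooth.  Increase the smoothing window
  for noisy data.
* The angle-of-attack sign convention is a package choice (snout-up
  positive); magnitudes are convention-free.
* The wave estimator assumes one dominant frequency; strongly
  multi-harmonic or accelerating swimming violates it (the standing-wave
  and power-threshold guards catch the worst cases).
* The generator's simplifications (no foreshortening, i.i.d. noise,
  fixed chord geometry) mean recovery tests bound estimator error under
  the model, not under all real-world failure modes.
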