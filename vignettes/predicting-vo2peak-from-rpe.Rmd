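---
title: "Predicting children's VO2peak from submaximal perceived exertion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting children's VO2peak from submaximal perceived exertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakrpe)
library(dplyr)
```

## The problem

Peak oxygen uptake (VO2peak, ml·kg⁻¹·min⁻¹) is the criterion measure of
cardiorespiratory fitness, but measuring it requires exercising a child to
volitional exhaustion — often unsuitable for clinical paediatric
populations. An alternative is to exploit the submaximal portion of a
single graded exercise test (GXT): children rate their effort at the end of
each stage on a perceived-exertion scale, the within-child relation between
rating and VO2 is fitted from the submaximal stages only, and the fit is
extrapolated to a rating representing exhaustion.

`peakrpe` implements this procedure for two paediatric rating scales:

* **CERT** (Children's Effort Rating Table, 1–10): the rating is modelled
  as linear in VO2, so each child's submaximal points are fitted by
  ordinary least squares,
  $\dot{V}O_2 = \beta_0 + \beta_1 \cdot \mathrm{RPE}$.
* **EP** (Eston–Parfitt scale, 0–10): the scale is deliberately
  curvilinear, so the relation is fitted as a power law via the log–log
  transform, $\log \dot{V}O_2 = \log a + b \log \mathrm{RPE}$, i.e.
  $\dot{V}O_2 = a \cdot \mathrm{RPE}^{\,b}$, and back-transformed for
  prediction.

Each fit uses the stages whose rating is at or below a submaximal
**ceiling** (5, a moderate intensity, or 7, a high intensity), and is
evaluated at two **endpoints**: the scale's theoretical maximum (10) and
the terminal rating children typically report at exhaustion (9). That
yields eight prediction conditions per child.

Predictions are compared against the measured criterion with the standard
validity battery: Pearson r with the conventional agreement bands
(r > 0.75 excellent, 0.4–0.75 fair-to-good), the standard error of
estimate (SEE) from the regression of measured on predicted, the SEE
standardized by the criterion SD with magnitude labels (< 0.2 trivial,
0.2–0.6 small, 0.6–1.2 moderate, 1.2–2.0 large, ≥ 2 very large), the
relative standard error (SEE as % of the criterion mean), paired t tests,
and a five-group one-way ANOVA (measured plus four prediction conditions
per ceiling family) with Bonferroni-adjusted post hoc contrasts against
the measured group.

## Modelling decisions that were genuinely open

Several choices are not fully determined by the procedure's usual
description; the package fixes them as follows.

* **Regression direction.** The perceptual fit takes VO2 as the response
  and the rating as the predictor. Extrapolation "to RPE 9/10" is only
  meaningful in this direction: the prediction is the fitted VO2 at a
  fixed rating.
* **"Up to and including" a ceiling** is a value filter, not a time
  prefix: every stage whose rating is ≤ the ceiling contributes, even if a
  higher rating occurred at an earlier stage (ratings need not be
  monotone under report noise). Repeated ratings enter as separate stage
  points; no averaging within a rating level.
* **EP ratings of 0** are excluded from the power fit (the logarithm is
  undefined at 0; at a running start speed a 0 report is not expected).
* **Logarithm base.** Natural logs are used. Predictions are provably
  base-invariant — refitting in base 10 changes the intercept but not the
  fitted power curve — so this only fixes the reported coefficient scale.
* **Minimum data rule.** A fit requires at least two points with at least
  two distinct ratings at or below the ceiling; otherwise the condition is
  recorded as `INSUFFICIENT_DATA` with no prediction, and the child drops
  out of that condition's row in the agreement report (hence per-row n).
* **SEE convention.** The SEE comes from regressing the measured criterion
  on the prediction, the standard convention in validity studies, and is
  standardized by the **criterion's** SD. The published magnitude bands are
  only coherent under the criterion-SD convention (e.g. 5.64/10.8 = 0.52,
  a "small" error); a `denominator = "predicted"` option exposes the
  alternative reading.
* **Per-row measured summaries.** Each report row summarises measured
  values over that condition's OK subset, which is why the measured column
  varies with n.
* **Post hoc procedure.** Pooled-variance pairwise t tests of each
  prediction condition against the measured group, Bonferroni-corrected
  for the four comparisons in the family — the simplest defensible choice
  matching the reported contrasts.
* **Pearson band gap.** Conventional wording leaves (0.74, 0.75]
  undefined; values there are labelled fair-to-good.
* **Degenerate statistics.** Identical paired vectors give t = 0, p = 1; a
  constant nonzero paired difference gives a signed infinite t with p = 0;
  a zero-variance ANOVA gives F = 0, p = 1; zero-variance correlations and
  regressions raise classed errors rather than returning NaN.

## Stage-level VO2

Breath-by-breath traces are reduced to one VO2 value per stage: the mean
over the **final 10 s** of the stage. The averaging window is half-open,
`(end − 10 s, end]`, so a sample on a stage boundary belongs to the ending
stage and is never double-counted. A partial final stage contributes a
stage value only if it spans at least 10 s — the protocol does not dictate
this, so the 10-s rule is the package's own cut, chosen to match the
averaging window.

## What the synthetic cohort emulates

No participant-level data accompany the procedure, so the package ships a
generator, `simulate_cohort()`, whose defaults encode the study
conditions; it is first-class, tested code, and every pipeline property is
verified against it.

* **Protocol**: treadmill stages of 60 s starting at 7 km/h, +0.5 km/h per
  stage, until VO2peak. Exhaustion is snapped to the 0.5 km/h stage grid
  (the nearest grid point to the child's latent continuous peak speed), so
  relative intensity reaches exactly 1 on the final stage; rounding to the
  nearest grid point keeps the cohort's mean peak speed unbiased, where
  always finishing the started stage would add ~0.25 km/h.
* **Peak physiology**: VO2peak ~ truncated normal (55.2 ± 10.8, bounds
  30–85 ml·kg⁻¹·min⁻¹), HRpeak ~ 203 ± 7 bpm (170–230), peak speed ~
  10.9 ± 1.2 km/h (8–14). Bounds are physiological-plausibility cuts for
  8–10-year-olds.
* **Within-child VO2** rises linearly with speed from a start intensity of
  0.62 × VO2peak at 7 km/h (a realistic running start for children of this
  fitness) to VO2peak at the final stage. All curvilinearity lives in the
  perceptual response, isolating the feature the two scales differ on.
* **Perceptual responses** at relative intensity x (VO2/VO2peak):
  CERT = 1 + 9·max(0, (x − x₀)/(1 − x₀)) with onset x₀ = 0.604, and
  EP = 10·x^γ with γ = 3.7198. The constants are the closed-form solutions
  of the anchor equations placing CERT 5 at 78 % and EP 5 at 83 % of
  VO2peak; they then put CERT 7 near 87 % and EP 7 near 91 %, consistent
  with the upper anchors. Both curves reach exactly 10 at x = 1, which
  makes the generator's responses the exact inverses of the two prediction
  models: with all noise at zero and rounding disabled, endpoint-10
  extrapolation recovers the latent VO2peak to machine precision — the
  pipeline's identifiability check. Per-child heterogeneity jitters x₀
  (SD 0.03, truncated below the start intensity so the floor is never
  inside the data range by default) and γ (log-scale SD 0.06, bounds
  2.5–5.5).
* **Noise.** Stage VO2 carries measurement noise of SD 1.5 ml·kg⁻¹·min⁻¹
  (typical for 10-s breath averages in children). Ratings carry report
  noise of SD 1.0 RPE unit, are rounded to integers and clipped to each
  scale's range. The top-of-scale censoring this induces reproduces the
  terminal-rating distribution: a latent rating of 10 plus unit noise,
  rounded and clipped, averages ≈ 9.6 with SD ≈ 0.7 on both scales. The
  criterion VO2peak is the terminal stage's measured VO2 — a single
  unbiased measurement-error draw — so the generator's cohort means stay
  calibrated to the configured targets; taking the maximum across noisy
  stages instead would bias the criterion upward by about half a
  millilitre.
* **Insufficient-data children.** With probability 0.15 a child perceives
  the start as already hard ("hot reporter": x₀ = 0.05, γ = 1.5), so their
  first CERT reports start above 5 and the ceiling-5 CERT window often
  holds fewer than two distinct ratings; the curvilinear EP response keeps
  its low range longer, so the EP ceiling-5 window is hit far less. This
  reproduces the qualitative pattern of differing per-condition n
  (ceiling-5 rows smaller than ceiling-7 rows, CERT affected more
  than EP).
* **Determinism.** A single explicit integer seed drives one RNG stream;
  the generator saves and restores the caller's RNG state, and identical
  configs give byte-identical CSVs.

What the generator does **not** emulate: breath-by-breath gas-exchange
kinetics (the optional 1 Hz trace is stagewise-constant plus white noise),
VO2 drift or slow components, sex/age effects on perception,
correlation between fitness and perceptual parameters, and — importantly —
any gap between the true terminal rating and the scale maximum: the latent
curves reach exactly 10 at exhaustion, the reported 9.6 arising purely
from noise censoring. Consequently, on synthetic data the endpoint-10
extrapolation is unbiased by construction and endpoint-9 predictions sit
slightly low; real children, whose true exhaustion rating falls short of
the scale maximum, show the opposite ordering. Passing tests on this
generator therefore demonstrate correctness of the estimators and
plumbing, not that every field finding is reproduced (see the README's
reproduction notes).

## Problem sizes and numerical tolerances

The test suite exercises study-sized cohorts (n = 50) for end-to-end
checks, n = 200 for calibration and ordering checks (chosen so that
two-standard-error bands on cohort means are tight, ~1.5 ml·kg⁻¹·min⁻¹ for
VO2peak), and n ≤ 30 fixtures for unit tests. Exact-recovery and oracle
comparisons use 1e-10 (coefficients against hand-written normal
equations) and 1e-6 (noise-free pipeline inversion). Comparisons against
published derived cells use a tolerance propagated from the printed
precision of the inputs (±0.015 on the standardized SEE, ±0.15 on the
RSE %), since a value printed as 10.1 may be anything in [10.05, 10.15).

## Limitations

* Per-child regressions need only two distinct submaximal ratings; with so
  few points the extrapolation variance is large, which is faithful to the
  procedure rather than a defect of the implementation.
* The agreement battery assumes one prediction per child per condition;
  repeated tests per child are out of scope, as are Bland–Altman limits
  and mixed-effects pooling.
* The ANOVA is the standard between-groups design; published error
  degrees of freedom that cannot be reproduced from the stated group
  sizes under that design are not chased.
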