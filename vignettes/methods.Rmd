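---
title: "Models and design choices in socioscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in socioscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(socioscope)
```

socioscope measures sociability in two assays — walking-fly groups and
semi-natural mouse colonies — and ships the simulators that make every
stage of the analysis testable against known ground truth. This
vignette records the models, their assumptions, and the decisions taken
where the design was genuinely open.

## 1. The fly interaction detector

A directed social interaction from an actor toward a target requires
three simultaneous conditions: the actor's body axis points within
`max_angle_deg` (default 90°) of the target's center, the
center-to-center distance is at most `max_dist_bl` (default 2) body
lengths, and both are maintained for at least `min_duration_s` (default
1.5 s). Scored this way, an interaction is the walking-fly analogue of
a mouse sniffing bout.

Decisions behind the implementation:

* **Comparison senses are taken literally**: strictly `<` for the
  angle, `≤` for the distance, `≥` for the duration. The boundary
  probes in `recover_angle_threshold()` and friends treat the detector
  as a black box and recover these senses bisectively, so a regression
  in any comparison flips a test.
* **Directionality.** The orientation condition involves only the
  actor's heading, so the predicate is asymmetric and events are
  directed; arena totals count ordered pairs. A `mutual = TRUE` switch
  scores only frames on which both directions hold and reports each
  unordered pair once, covering the alternative reading of a
  "reciprocal" interaction.
* **Durations are frame counts** divided by the frame rate — no
  sub-frame interpolation. An episode qualifies iff
  `run_frames / frame_rate_hz >= min_duration_s`. This is deterministic
  and tracker-native, and it makes the duration boundary exactly
  representable at probe frame rates that divide the threshold (the
  duration probe runs at 10 Hz so 0.1 s steps are exact).
* **Tracking gaps split runs by default** (`gap_tolerance_frames = 0`),
  the conservative reading; bridging is opt-in. Gap handling lives in
  the detector, not the reader: the reader only records a validity
  mask and never interpolates.
* **Body-length mode.** The proximity threshold is expressed in body
  lengths without an owner; the default uses the actor's body length,
  `mean_pair` is available. Per-individual lengths are medians of
  per-frame posture lengths (robust to segmentation blow-ups), with a
  configured constant as fallback.
* **Speed** is path length over valid consecutive-frame steps divided
  by the observed time on those steps; steps spanning a gap are
  excluded so re-entry jumps cannot inflate locomotion.

Note that event *counts* are not pointwise monotone in the thresholds
for a fixed recording — widening a threshold can merge two runs into
one — so the monotonicity checks in the test suite average counts over
simulated recordings, where the expected ordering holds with large
margins.

## 2. Fly group statistics

The arena (one group of four flies over one 10-minute recording) is the
unit of analysis; per-fly values are never treated as independent
replicates. Each response is screened with a Shapiro–Wilk test at
α = 0.05; speed is modeled with a gaussian linear model, interaction
counts with a log-link Poisson GLM and per-event mean durations with a
log-link Gamma GLM, all as `response ~ sex + genotype`. Both per-term
type-II analysis-of-deviance tests (each term adjusted for the other)
and the joint 2-df test of both design terms are reported, since
practice varies in which is quoted. No multiplicity correction is
applied, matching common practice for these panels.

## 3. Colony binning and the injection design

Event logs carry half-open `[start_s, stop_s)` spans. Hourly binning
apportions each event to bins by exact overlap, so the total duration
is conserved to floating-point accuracy — an invariant the tests check
to 1e-9 s. Social behaviors aggregate over all conspecific targets;
`direction = "received"` re-keys events on the target to quantify
passive social exposure. Distance increments (`distance_step`, cm) bin
their magnitude proportionally to time overlap.

Phase is a function of `hour %% 24` and a configured dark onset only.
The default places dark at hours 0–11 of each experimental day, which
matches designs where animals enter the arena (or are injected) just
before dark onset; the onset is configurable because only relative
clock times are meaningful here.

The log transform is `log(value + 1 s)`. Hourly totals of a behavior
are sums of a random number of bout durations and are right-skewed with
exact zeros; a 1 s offset is negligible against typical totals of tens
to hundreds of seconds and makes zeros finite. The offset is stored on
the transformed object so the transform is invertible.

For pharmacological designs the analysis object is the hour-matched
baseline delta, `Δ(h) = y(t_inj + h) − y(t_inj − 24 + h)` for
`h = 0..23`. Because the photoperiod is 24 h, matched hours share a
phase and the subtraction removes each subject's circadian baseline;
the delta is exactly equivariant under constant post-injection shifts.

## 4. The penalized-spline contrast engine

Per group, the hourly series is modeled as

`y_it = f(t) + b_i + beta * x_it + e_it`

* `f` is a cubic B-spline of dimension k = 30 over 144 hours with a
  second-order difference penalty. k = 30 resolves features at the
  ~5-hour scale — enough for within-phase structure, coarse enough to
  be estimable from a handful of subjects; heavy smoothing collapses
  `f` onto the penalty null space (a line). The penalty weight is
  chosen by GCV on a fixed grid of 41 log-spaced values (1e-2 to 1e8)
  — deterministic, no random restarts.
* `b_i` are ridge-penalized subject intercepts (default weight 1).
  With 4–8 subjects per group, full random-effects machinery adds
  little over shrunken fixed intercepts, and this keeps the estimator
  self-contained and directly testable.
* `x_it` is the nest covariate. Social behavior cannot be observed
  while a subject is nested, so the expected hourly total scales with
  the out-of-nest fraction of the hour; on the log scale this is the
  additive term `log((3600 − nest_s)/3600)` with slope near one, the
  default `nest_form = "log_available"`. Besides being the correct
  functional form, it absorbs most of the serial dependence that
  multi-hour nest bouts would otherwise leave in the residuals — with
  a raw-seconds covariate the pointwise intervals of the difference
  curve were visibly too narrow in null simulations.
* **Heteroscedasticity.** Circadian series mix near-empty light-phase
  bins with busy dark-phase bins; a constant dispersion miscalibrates
  pointwise intervals. Gaussian fits therefore estimate a working
  residual variance per hour of day (pooled by phase when fewer than
  ~20 replicates per hour exist) and refit with inverse-variance
  weights. Quasipoisson fits (used for distance series) instead carry
  a free Pearson dispersion through penalized IRLS with a log link.
* **Covariance.** Intervals use the penalized-likelihood ("Bayesian")
  coefficient covariance `(XᵀWX + P)⁻¹ φ`. A by-subject sandwich
  covariance is available (`cov_type = "cluster_robust"`) but is not
  the default: with ~38 coefficients against 7 subjects the sandwich
  is badly biased low.

The difference curve is `f_A(t) − f_B(t)` with pointwise variance
summed from the two independent fits; hours whose 95% interval
excludes zero are flagged, deliberately without multiplicity
correction — a flagged hour is a pointwise statement, mirroring how
difference plots are read. The curve is exactly antisymmetric in the
group order.

`analyze_contrast()` adds two tests:

* **Group × time interaction**: an F-type comparison of separate
  per-group smooths against one shared smooth plus a constant group
  offset, on effective degrees of freedom, computed on unweighted
  residual sums so the nested fits are on a common scale.
* **Overall group effect**: a Welch t-test on per-subject mean
  responses (link scale for counts). This is the Wald test of the
  group mean offset that respects between-subject variance under
  repeated measures; the curve-based Wald statistic is also attached
  to the difference curve for completeness.

Null calibration of all three outputs (pointwise flags ≈ 5% of hours,
uniform overall p-values) is verified by simulation in the acceptance
suite at 200 seeds.

For the injection design the same engine runs on the 24-hour delta
series with k = 10. "No systematic flag" in the vehicle arm is read as
(a) the mean early-window delta-difference centered at zero and (b) a
flagged-negative rate far below the drug arm — a guarantee that any
pointwise-interval procedure can actually make, unlike "no flagged
hour anywhere", which over 24 correlated pointwise tests fails a
non-trivial fraction of true nulls by construction.

## 5. The simulators

**Flies.** Each fly performs a correlated random walk: per-frame
wrapped-normal turns with standard deviation
`1/sqrt(heading_persistence)` rad, truncated-normal speeds, specular
reflection at the walls, and an attraction term that relaxes the
heading toward the nearest neighbour at rate `attraction_strength ×
4.5 s⁻¹` of the bearing error (capped at full reorientation per
frame). The rate cap encodes a finite turning velocity: flies pursue in
bouts rather than locking onto a neighbour instantaneously, which is
both more realistic and what makes event counts rise with attraction
instead of fusing into a single interminable episode. Bodies are
mutually exclusive: overlapping flies are pushed apart to one body
length, a hard-core constraint without which converged pairs jitter
through each other and their relative bearing decorrelates frame to
frame. Defaults (4 flies, 600 s at 30 Hz, 8 ± 4 mm/s speeds, 2.5 mm
bodies, 66 × 40 mm arena) describe the standard group assay.

**Colonies.** Per subject and behavior, events arrive as an
inhomogeneous Poisson process with hourly rate = base rate × dark
multiplier (default 2.5 in dark hours; mice are nocturnal) × any
planted effect multipliers. Durations are lognormal (median 8 s,
σ = 0.6 log-units); distance steps carry lognormal cm magnitudes.
Nest occupancy is an alternating renewal process whose mean bout
lengths depend on phase (long nest bouts in the light/rest phase), and
social events starting during a nest bout are deleted — suppression is
*generated*, not merely observed, so the nest covariate has a real
confound to correct. Base rates (sniff 10/h, approach 12/h, distance
60/h in light) are chosen for statistical realism — hourly totals of
the right order with workable signal-to-noise at 4–8 subjects — since
no reference rates are available to match. Every generator is
bit-reproducible given its parameters: each subject draws from its own
counter-based substream, so adding an individual never perturbs the
others (target labels use an inverse-CDF draw for the same reason).

The injection generator lays out the standard staggered twin-arena
design: injections every third day at dark onset starting day 3, the
treated subject's rates multiplied for a fixed post-injection window,
and a vehicle twin arena with matched timing and no rate change. Drug
effects are multiplicative steps on the rate scale — aligned with the
log-scale analyses — with no pharmacokinetic decay.

**What the simulators do not emulate.** Fly locomotion has no
biomechanics (no saccades, grooming, wall-following); colonies have no
dominance structure, no inter-subject behavioral correlation beyond
shared nest geometry, no subject-level rate heterogeneity, and no
drug kinetics. Passing tests therefore certify the *pipeline* —
detection, binning, estimation, calibration, localization — under a
plausible generative model, not the biological fidelity of any
particular dataset.

## 6. Numerical notes and degenerate inputs

* Headings are wrapped into `[-π, π)` everywhere; angle comparisons use
  wrapped differences, so ±180° is not a special case.
* Spline boundary knots are nudged outward by 1e-6 of the range so
  every observation stays strictly inside the basis support despite
  floating-point knot arithmetic.
* A constant response is fitted exactly (to 1e-6) for any penalty
  weight; a constant vector is a hard error in the Shapiro–Wilk gate
  (W is undefined); zero events make the mean event duration `NA`, an
  explicit undefined marker rather than 0.
* Overlapping nest bouts are merged with a warning before binning, so
  no hourly nest value can exceed 3600 s.
* Colliding (id, frame) pairs, non-monotone frames, out-of-arena
  positions and unknown behavior labels are hard errors at the reading
  boundary, not silent repairs.

## 7. Problem sizes in the test suite

The suite exercises the study-scale conditions the generators define:
7-vs-7-subject colony contrasts over 6 days (144 h), with 200 seeds for
null calibration, 100 for effect localization and 100 per arm for the
injection comparison; fly checks run the full 10-minute arena where the
quantity under test needs it and 2–5-minute arenas for seed-averaged
monotonicity. Oracle equivalence is exact on 200 random tracksets of
100–1000 frames.

## 8. Known limitations

* The interaction detector implements exactly one behavior class; no
  lunging/courtship scoring and no social-network construction.
* The smooth engine fits independent groups; it has no AR(1) residual
  model. Intervals are pointwise by default; the simultaneous band
  (`band = "simultaneous"` in `difference_curve()`) is off by default
  to mirror how difference plots are read in practice.
* The mouse behavior classifiers themselves (how "sniff" is decided
  from RFID and video) are upstream of this package: event logs are
  consumed as given.
* With fewer than three subjects per group the contrast engine refuses
  to fit rather than produce uninterpretable intervals.
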