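# socioscope

Quantitative tools for measuring sociability — an animal's tendency to
seek and engage in affiliative contact with conspecifics — in two
complementary assays:

* **Fly arenas.** Groups of four walking flies in a 66 × 40 mm arena,
  observed for 10 minutes through a tracker (TRex-style per-frame
  exports). A directed *social interaction* from fly *i* toward fly *j*
  is scored when, simultaneously,

  1. the angle between fly *i*'s body axis and the vector to fly *j*'s
     center is **< 90°**,
  2. the center-to-center distance is **≤ 2 body lengths**, and
  3. both conditions are maintained for **≥ 1.5 s**,

  the walking-fly analogue of a mouse sniffing bout. Arena-level counts,
  per-event mean durations and locomotion are then modeled per sex as
  `response ~ sex + genotype` with a gaussian linear model (speed), a
  log-link Poisson GLM (counts) or a log-link Gamma GLM (durations),
  gated by a Shapiro–Wilk normality screen.

* **Mouse colonies.** Four-mouse groups living undisturbed for days in a
  semi-natural arena under a 12:12 light/dark cycle, with RFID-assisted
  annotation producing an event log (sniff, approach, nest occupancy,
  distance increments). Events are binned into hourly per-subject series
  `y_{it}`; social durations are modeled on the `log(y + 1)` scale as

  `y_{it} = f_g(t) + b_i + beta * nest_it + e_{it}`

  with `f_g` a cubic B-spline (k = 30 over 144 h) carrying a
  second-order difference penalty whose weight is chosen by GCV, `b_i`
  ridge-penalized subject intercepts, and a nest-occupancy covariate
  (social behavior is unobservable while a subject is nested). Group
  differences are read off the **difference curve**
  `f_KO(t) − f_WT(t)` with pointwise 95% intervals, an F-type test of
  the group × time interaction, and an overall group-offset test.
  Injection (drug vs vehicle, twin-arena counterbalanced) designs are
  analyzed on hour-matched **baseline deltas**:
  `Δ(h) = y(t_inj + h) − y(t_inj − 24 + h)`, `h = 0..23`.

Both input kinds can be simulated with known ground truth — a correlated
random walk with nearest-neighbour attraction for flies, an
inhomogeneous Poisson event process with circadian rate modulation and
nest suppression for colonies — so every stage of the pipeline is
verifiable without animal data.

## Worked example: fly arena

```r
library(socioscope)

ts <- simulate_fly_arena(sim_fly_params(attraction_strength = 0.6,
                                        duration_s = 600, seed = 8))
ev <- detect_interactions(ts)        # 90 deg / 2 BL / 1.5 s defaults
head(ev, 3)
#>   actor_id target_id start_frame end_frame duration_s
#> 1 fly_4    fly_3             126       191       2.17
#> 2 fly_4    fly_3             501       546       1.5
#> 3 fly_3    fly_4             605       680       2.5

summarize_group(ts, ev)
#>   n_interactions mean_duration_s total_distance_cm mean_speed_mm_s
#> 1             79        1.903376          1855.113        7.730065
```

79 directed interactions were detected over the 10-minute recording,
lasting 1.9 s on average; the four flies walked 18.6 m in total at a
mean speed of 7.7 mm/s. `fit_group_model()` then takes one such summary
row per arena and returns per-term type-II statistics plus the joint
2-df test.

## Worked example: mouse colony contrast

```r
library(dplyr)
mk <- function(seed, grp, prefix, eff = list()) {
  p <- sim_colony_params(n_subjects = 7, seed = seed, effect_spec = eff)
  log <- simulate_mouse_colony(p, behaviors = "sniff", subject_prefix = prefix)
  bin_durations(log, "sniff", 144) |>
    left_join(nest_covariate(log, 144), by = c("subject_id", "hour")) |>
    mutate(nest_s = coalesce(nest_s, 0), group = grp)
}
eff <- list(list(behavior = "sniff",
                 hours = c(24:35, 48:59, 72:83),   # dark phase, days 2-4
                 multiplier = 1.6))
dat <- bind_rows(mk(42, "KO", "k", eff), mk(142, "WT", "w")) |> log_transform()
fit <- analyze_contrast(dat, k = 30, family = "gaussian")
fit
#> <contrast_fit> KO vs WT  [gaussian, k = 30]
#>   interaction: F = 2.09 (edf 60.8 vs 38.5), p = 0.00204
#>   overall: t = -0.08, df = 11.1, p = 0.941
#>   flagged hours: 44 of 144
autoplot(fit)   # difference curve with flagged timepoints
```

The planted dark-phase sniffing increase in the knockout group is picked
up exactly as such analyses report it in practice: a clearly significant
group × time interaction (p ≈ 0.002) localized to the planted hours by
the difference curve, with no overall offset (p ≈ 0.94) because the
effect is confined to a third of the recording.

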