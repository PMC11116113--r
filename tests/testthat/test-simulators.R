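test_that("fly generator is bit-reproducible and respects arena bounds", {
  p <- sim_fly_params(duration_s = 30, seed = 99)
  ts1 <- simulate_fly_arena(p)
  ts2 <- simulate_fly_arena(p)
  expect_identical(ts1$x_mm, ts2$x_mm)
  expect_identical(ts1$heading_rad, ts2$heading_rad)
  for (s in 1:10) {
    ts <- simulate_fly_arena(sim_fly_params(duration_s = 20, seed = s))
    expect_true(all(ts$x_mm >= 0 & ts$x_mm <= 66))
    expect_true(all(ts$y_mm >= 0 & ts$y_mm <= 40))
    expect_true(all(ts$heading_rad >= -pi & ts$heading_rad < pi))
  }
})

test_that("zero mean speed produces stationary flies and no interactions", {
  ts <- simulate_fly_arena(sim_fly_params(mean_speed_mm_s = 0,
                                          speed_sd_mm_s = 0,
                                          duration_s = 60, seed = 4))
  d <- ts |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(moved = max(x_mm) - min(x_mm) + max(y_mm) - min(y_mm))
  expect_true(all(d$moved == 0))
  gs <- summarize_group(ts)
  expect_equal(gs$n_interactions, 0)
  expect_equal(gs$total_distance_mm, 0)
})

test_that("turning angles follow the wrapped-normal spec (circular variance)", {
  # lone fly in a huge arena: no walls, no neighbours, pure random walk
  big <- arena_config(width_mm = 5e4, height_mm = 5e4)
  kappa <- 10
  p <- sim_fly_params(n_flies = 1, duration_s = 100000 / 30,
                      heading_persistence = kappa, attraction_strength = 0,
                      arena = big, seed = 12)
  ts <- simulate_fly_arena(p)
  turns <- wrap_angle(diff(ts$heading_rad))
  cv <- 1 - mean(cos(turns))
  expect_equal(cv, 1 - exp(-(1 / kappa) / 2), tolerance = 0.01)
})

test_that("planted episodes are recovered exactly by the detector", {
  base <- static_trackset(data.frame(id = c("A", "B"), x = c(5, 60),
                                     y = c(5, 35), heading = c(0, 0)),
                          n_frames = 600)
  expect_equal(nrow(detect_interactions(base)), 0)
  # one supra- and one sub-threshold episode: only the 2 s one survives
  ts <- plant_interaction_episodes(
    base, data.frame(actor = "A", target = "B",
                     start_s = c(2, 10), duration_s = c(2, 1)))
  ev <- detect_interactions(ts)
  ev <- ev[ev$actor_id == "A", ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 2)
  expect_equal(ev$start_frame, 60L)
  # ten disjoint 2 s episodes, spaced wider than the separation buffer
  long_base <- static_trackset(data.frame(id = c("A", "B"), x = c(5, 60),
                                          y = c(5, 35), heading = c(0, 0)),
                               n_frames = 780)
  many <- plant_interaction_episodes(
    long_base, data.frame(actor = "A", target = "B",
                          start_s = seq(0.1, by = 2.5, length.out = 10),
                          duration_s = 2))
  expect_equal(sum(detect_interactions(many)$actor_id == "A"), 10)
  expect_error(
    plant_interaction_episodes(base, data.frame(actor = "A", target = "B",
                                                start_s = 25, duration_s = 2)),
    "outside")
  expect_error(
    plant_interaction_episodes(base, data.frame(actor = "A", target = "B",
                                                start_s = c(1, 2),
                                                duration_s = c(2, 2))),
    "overlapping")
})

test_that("colony generator is reproducible and per-subject substreams are stable", {
  p <- sim_colony_params(days = 2, seed = 31)
  l1 <- simulate_mouse_colony(p)
  l2 <- simulate_mouse_colony(p)
  expect_identical(l1, l2)
  # adding a subject leaves existing subjects' event times untouched
  p5 <- sim_colony_params(n_subjects = 5, days = 2, seed = 31)
  l5 <- simulate_mouse_colony(p5)
  for (s in c("m1", "m3")) {
    a <- l1[l1$subject_id == s, c("behavior", "start_s", "stop_s")]
    b <- l5[l5$subject_id == s, c("behavior", "start_s", "stop_s")]
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("a 6-day colony bins to 144 hours, half of them dark", {
  p <- sim_colony_params(days = 6, seed = 17)
  log <- simulate_mouse_colony(p, behaviors = "sniff")
  b <- bin_durations(log, "sniff", 144)
  hours <- unique(b[, c("hour", "phase")])
  expect_equal(nrow(hours), 144)
  expect_equal(sum(hours$phase == "dark"), 72)
})

test_that("realized hourly event counts match the specified intensity", {
  # without nest suppression the counts are exactly Poisson(rate)
  rej <- vapply(1:20, function(s) {
    p <- sim_colony_params(n_subjects = 1, days = 4,
                           dark_intensity_multiplier = 2,
                           suppress_in_nest = FALSE, seed = 400 + s)
    log <- simulate_mouse_colony(p, behaviors = "sniff")
    counts <- table(factor(floor(log$start_s / 3600), levels = 0:95))
    rate <- rep(10, 96)
    rate[hour_phase(0:95) == "dark"] <- 20
    stat <- sum((as.numeric(counts) - rate)^2 / rate)
    stat > qchisq(0.99, df = 96)
  }, logical(1))
  expect_gte(mean(!rej), 0.9)
})

test_that("dark multiplier 1 removes the circadian contrast", {
  p <- sim_colony_params(dark_intensity_multiplier = 1,
                         suppress_in_nest = FALSE, days = 6, seed = 23)
  b <- bin_durations(simulate_mouse_colony(p, behaviors = "sniff"),
                     "sniff", 144)
  tt <- t.test(b$value[b$phase == "dark"], b$value[b$phase == "light"])
  expect_gt(tt$p.value, 0.01)
})

test_that("nest suppression removes events that start inside nest bouts", {
  p <- sim_colony_params(days = 2, seed = 5)
  log <- simulate_mouse_colony(p)
  nests <- log[log$behavior == "in_nest", ]
  social <- log[log$behavior %in% c("sniff", "approach"), ]
  for (s in unique(social$subject_id)) {
    iv <- nests[nests$subject_id == s, ]
    st <- social$start_s[social$subject_id == s]
    inside <- vapply(st, function(x) any(x >= iv$start_s & x < iv$stop_s),
                     logical(1))
    expect_false(any(inside))
  }
})

test_that("the injection design staggers treatments and validates its horizon", {
  p <- sim_colony_params(n_subjects = 4, days = 15, seed = 3)
  sim <- simulate_injection_experiment(p, behaviors = "sniff")
  expect_equal(nrow(sim$schedule), 8)
  expect_equal(sim$schedule$injection_hour[1:4], c(48, 120, 192, 264))
  expect_setequal(unique(sim$schedule$treatment), c("drug", "vehicle"))
  # twin pairing is symmetric
  expect_equal(unique(sim$schedule$arena_id[sim$schedule$treatment == "drug"]), "A")
  expect_equal(unique(sim$schedule$twin_arena_id[sim$schedule$treatment == "drug"]), "B")
  short <- sim_colony_params(n_subjects = 4, days = 6, seed = 3)
  expect_error(simulate_injection_experiment(short), "horizon")
})

test_that("parameter validation rejects degenerate simulator settings", {
  expect_error(sim_fly_params(heading_persistence = 0), "positive")
  expect_error(sim_fly_params(attraction_strength = -1), ">= 0")
  expect_error(sim_colony_params(dark_intensity_multiplier = 0.5), "multiplier")
  expect_error(sim_colony_params(effect_spec = list(list(behavior = "sniff",
                                                         hours = 0:5))),
               "multiplier")
  expect_error(sim_colony_params(days = 1,
                                 effect_spec = list(list(behavior = "sniff",
                                                         hours = 30:40,
                                                         multiplier = 2))),
               "outside")
})
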