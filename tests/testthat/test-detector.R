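# body length is 2.5 mm in all fixtures, so 1 BL = 2.5 mm

test_that("the geometric predicate honors the angle (strict) and distance (inclusive) thresholds", {
  mk <- function(target_dx, target_dy, actor_heading = 0) {
    static_trackset(data.frame(
      id = c("A", "B"), x = c(20, 20 + target_dx), y = c(20, 20 + target_dy),
      heading = c(actor_heading, pi)), n_frames = 5)
  }
  bl <- 2.5
  # ahead at 1.5 BL: bearing 0, distance ok
  expect_true(frame_predicate(mk(1.5 * bl, 0), "A", "B", 0))
  # behind the actor: bearing error 180 degrees
  expect_false(frame_predicate(mk(1.5 * bl, 0, actor_heading = pi), "A", "B", 0))
  # exactly on the 90-degree boundary: strict inequality fails
  expect_false(frame_predicate(mk(0, 1.5 * bl), "A", "B", 0))
  # just inside the boundary
  expect_true(frame_predicate(mk(1e-6, 1.5 * bl), "A", "B", 0))
  # distance exactly 2 BL is inclusive; epsilon beyond is out
  expect_true(frame_predicate(mk(2 * bl, 0), "A", "B", 0))
  expect_false(frame_predicate(mk(2 * bl + 1e-9, 0), "A", "B", 0))
  # the predicate is directional: B here faces A (heading pi), so B->A
  # holds; with B turned away it does not, while A->B is unaffected
  expect_true(frame_predicate(mk(1.5 * bl, 0), "B", "A", 0))
  away <- static_trackset(data.frame(id = c("A", "B"),
                                     x = c(20, 20 + 1.5 * bl), y = 20,
                                     heading = c(0, 0)), n_frames = 5)
  expect_false(frame_predicate(away, "B", "A", 0))
  expect_true(frame_predicate(away, "A", "B", 0))
  expect_error(frame_predicate(mk(1, 0), "A", "A", 0), "differ")
  expect_error(frame_predicate(mk(1, 0), "A", "nope", 0), "unknown")
  expect_error(frame_predicate(mk(1, 0), "A", "B", 99), "domain")
})

test_that("duration gating uses frame counts against the configured frame rate", {
  # 44 frames at 30 Hz = 1.467 s: below threshold; 45 frames = 1.5 s: one event
  short <- two_fly_configuration(0, 1, 44 / 30, frame_rate_hz = 30)
  long <- two_fly_configuration(0, 1, 45 / 30, frame_rate_hz = 30)
  expect_equal(sum(detect_interactions(short)$actor_id == "actor"), 0)
  ev <- detect_interactions(long)
  ev <- ev[ev$actor_id == "actor", ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 1.5)
  expect_equal(ev$end_frame - ev$start_frame, 45L)
})

test_that("far-apart or stationary flies yield no events", {
  ts <- static_trackset(data.frame(id = c("A", "B"), x = c(5, 60),
                                   y = c(5, 35), heading = c(0, 0)),
                        n_frames = 600)
  expect_equal(nrow(detect_interactions(ts)), 0)
})

test_that("a tracking gap splits a run unless gap tolerance bridges it", {
  # stationary interacting pair; actor untracked on exactly frame 30
  n <- 60
  df <- expand.grid(id = c("A", "B"), frame = 0:(n - 1))
  df$x <- ifelse(df$id == "A", 20, 22.5)
  df$y <- 20
  df$heading <- ifelse(df$id == "A", 0, pi)
  df <- df[!(df$id == "A" & df$frame == 30), ]
  ts <- as_trackset(df, arena_config(frame_rate_hz = 30),
                    body_length_mm = 2.5)
  strict <- detect_interactions(ts)                       # runs of 30 and 29
  expect_equal(sum(strict$actor_id == "A"), 0)
  bridged <- detect_interactions(ts, detector_params(gap_tolerance_frames = 1))
  bridged <- bridged[bridged$actor_id == "A", ]
  expect_equal(nrow(bridged), 1)
  expect_equal(bridged$duration_s, 2)
})

test_that("mutual mode requires both directions and reports unordered pairs once", {
  facing <- static_trackset(data.frame(id = c("A", "B"), x = c(20, 22.5),
                                       y = 20, heading = c(0, pi)),
                            n_frames = 60)
  oneway <- static_trackset(data.frame(id = c("A", "B"), x = c(20, 22.5),
                                       y = 20, heading = c(0, 0)),
                            n_frames = 60)
  expect_equal(nrow(detect_interactions(facing, detector_params(mutual = TRUE))), 1)
  expect_equal(nrow(detect_interactions(oneway, detector_params(mutual = TRUE))), 0)
  # directed default sees two events in the facing configuration
  expect_equal(nrow(detect_interactions(facing)), 2)
})

test_that("detection matches the brute-force oracle on random tracksets", {
  n_events <- 0
  for (s in 1:25) {
    ts <- random_trackset(s, n_frames = 200 + (s %% 5) * 100)
    ev <- detect_interactions(ts)
    expect_identical(ev, oracle_detect(ts))
    n_events <- n_events + nrow(ev)
  }
  expect_gt(n_events, 0)   # the comparison must bite, not match empties
  # off the conservative defaults: shorter episodes, bridged gaps
  params <- detector_params(min_duration_s = 0.5, gap_tolerance_frames = 2)
  n_events <- 0
  for (s in 1:10) {
    ts <- random_trackset(100 + s, n_frames = 300, gap_prob = 0.05)
    ev <- detect_interactions(ts, params)
    expect_identical(ev, oracle_detect(ts, params))
    n_events <- n_events + nrow(ev)
  }
  expect_gt(n_events, 0)
})

test_that("events are invariant under rigid motions of the whole arena", {
  ts <- simulate_fly_arena(sim_fly_params(attraction_strength = 0.8,
                                          duration_s = 60, seed = 14))
  ev <- detect_interactions(ts)
  expect_gt(nrow(ev), 0)   # fixture must exercise the property
  th <- 0.7
  ts2 <- ts
  x <- ts$x_mm; y <- ts$y_mm
  ts2$x_mm <- cos(th) * x - sin(th) * y + 12
  ts2$y_mm <- sin(th) * x + cos(th) * y - 3
  ts2$heading_rad <- wrap_angle(ts$heading_rad + th)
  expect_identical(detect_interactions(ts2), ev)
})

test_that("per-ordered-pair interacting time never exceeds the recording", {
  for (s in 1:5) {
    ts <- random_trackset(50 + s, n_frames = 250)
    dur <- arena(ts)$frame_rate_hz^-1 * 250
    tot <- detect_interactions(ts, detector_params(min_duration_s = 0)) |>
      dplyr::group_by(actor_id, target_id) |>
      dplyr::summarise(t = sum(duration_s), .groups = "drop")
    if (nrow(tot) > 0) expect_lte(max(tot$t), dur)
  }
})

test_that("group summaries compute counts, durations, distance and speed", {
  ts <- static_trackset(data.frame(id = c("A", "B"), x = c(5, 60),
                                   y = c(5, 35), heading = c(0, 0)),
                        n_frames = 100)
  planted <- tibble::tibble(actor_id = c("A", "B"), target_id = c("B", "A"),
                            start_frame = c(0L, 10L), end_frame = c(60L, 100L),
                            duration_s = c(2, 3))
  gs <- summarize_group(ts, planted)
  expect_equal(gs$n_interactions, 2)
  expect_equal(gs$mean_duration_s, 2.5)
  # stationary flies: zero distance and speed
  expect_equal(gs$total_distance_mm, 0)
  expect_equal(gs$mean_speed_mm_s, 0)
  # no events: the undefined-mean marker is NA
  gs0 <- summarize_group(ts, detect_interactions(ts))
  expect_equal(gs0$n_interactions, 0)
  expect_true(is.na(gs0$mean_duration_s))
})

test_that("speed is path length over observed time, excluding gap-spanning steps", {
  # 1 mm per frame at 30 Hz -> 30 mm/s
  n <- 50
  df <- data.frame(id = "A", frame = 0:(n - 1), x = 5 + 0:(n - 1), y = 20,
                   heading = 0)
  ts <- as_trackset(df, arena_config(), body_length_mm = 2.5)
  ind <- summarize_individuals(ts, detect_interactions(ts))
  expect_equal(ind$mean_speed_mm_s, 30)
  expect_equal(ind$total_distance_mm, n - 1)
  # knock out a frame: the two steps crossing it are discarded
  df2 <- df[df$frame != 25, ]
  ts2 <- as_trackset(df2, arena_config(), body_length_mm = 2.5)
  ind2 <- summarize_individuals(ts2, detect_interactions(ts2))
  expect_equal(ind2$total_distance_mm, n - 3)
  expect_equal(ind2$mean_speed_mm_s, 30)   # rate unchanged, time excluded too
})

test_that("detector parameters validate their ranges", {
  expect_error(detector_params(max_angle_deg = 0), "0, 180")
  expect_error(detector_params(max_angle_deg = 181), "0, 180")
  expect_error(detector_params(max_dist_bl = 0), "positive")
  expect_error(detector_params(min_duration_s = -1), ">= 0")
  expect_error(detector_params(gap_tolerance_frames = -1), "non-negative")
})
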