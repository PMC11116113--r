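# shared fixture builders; everything is generated in code at test time

# trackset in which every individual holds one pose for the whole recording
static_trackset <- function(poses, n_frames = 60, frame_rate_hz = 30,
                            body_length_mm = 2.5) {
  a <- arena_config(frame_rate_hz = frame_rate_hz)
  df <- do.call(rbind, lapply(seq_len(nrow(poses)), function(i) {
    data.frame(id = poses$id[i], frame = seq_len(n_frames) - 1L,
               x = poses$x[i], y = poses$y[i], heading = poses$heading[i])
  }))
  as_trackset(df, a, body_length_mm = body_length_mm)
}

# adversarial random trackset: per-fly clipped random walks with slowly
# drifting headings and optional gaps, so runs of predicate-true frames
# of every length actually occur; deliberately not built with the
# package's movement simulator
random_trackset <- function(seed, n_frames = 300, n_flies = 4,
                            frame_rate_hz = 30, gap_prob = 0.02) {
  a <- arena_config(frame_rate_hz = frame_rate_hz)
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(n_flies), function(i) {
    x <- pmin(pmax(cumsum(c(runif(1, a$width_mm / 2 - 10, a$width_mm / 2 + 10),
                            rnorm(n_frames - 1, 0, 0.3))), 0), a$width_mm)
    y <- pmin(pmax(cumsum(c(runif(1, a$height_mm / 2 - 10, a$height_mm / 2 + 10),
                            rnorm(n_frames - 1, 0, 0.3))), 0), a$height_mm)
    h <- wrap_angle(cumsum(c(runif(1, -pi, pi), rnorm(n_frames - 1, 0, 0.1))))
    keep <- runif(n_frames) >= gap_prob
    keep[1] <- TRUE   # keep a common frame domain
    data.frame(id = sprintf("f%d", i), frame = which(keep) - 1L,
               x = x[keep], y = y[keep], heading = h[keep])
  }))
  as_trackset(df, a, body_length_mm = 2.5)
}

# brute-force reference detector: per-frame predicate scan with an
# explicit state machine (including gap bridging), independent of the
# run-merging arithmetic in detect_interactions
oracle_detect <- function(ts, params = detector_params()) {
  fps <- arena(ts)$frame_rate_hz
  ids <- sort(unique(ts$individual_id))
  n <- max(ts$frame) + 1L
  g <- params$gap_tolerance_frames
  out <- list()
  for (actor in ids) {
    for (target in setdiff(ids, actor)) {
      ok <- frame_predicate(ts, actor, target, 0:(n - 1), params)
      ok[is.na(ok)] <- FALSE
      start <- NA
      last_true <- NA
      off <- 0L
      for (f in 0:n) {
        on <- f < n && ok[f + 1]
        if (on) {
          if (is.na(start)) start <- f
          last_true <- f
          off <- 0L
        } else if (!is.na(start)) {
          off <- off + 1L
          if (off > g || f == n) {
            end <- last_true + 1L
            if ((end - start) / fps >= params$min_duration_s) {
              out[[length(out) + 1]] <- data.frame(
                actor_id = actor, target_id = target,
                start_frame = start, end_frame = end,
                duration_s = (end - start) / fps)
            }
            start <- NA
            last_true <- NA
            off <- 0L
          }
        }
      }
    }
  }
  ev <- dplyr::bind_rows(out)
  if (nrow(ev) == 0) {
    return(tibble::tibble(actor_id = character(), target_id = character(),
                          start_frame = integer(), end_frame = integer(),
                          duration_s = double()))
  }
  ev <- dplyr::arrange(tibble::as_tibble(ev), start_frame, actor_id, target_id)
  ev$start_frame <- as.integer(ev$start_frame)
  ev$end_frame <- as.integer(ev$end_frame)
  ev
}

# one genotype group of sniff series: n independent experimental subjects
# (one per colony), binned, with the nest covariate attached
make_sniff_group <- function(seed, group, prefix, n_subjects = 7,
                             hours = 144, effect_spec = list()) {
  p <- sim_colony_params(n_subjects = n_subjects, days = hours / 24,
                         seed = seed, effect_spec = effect_spec)
  log <- simulate_mouse_colony(p, behaviors = "sniff",
                               subject_prefix = prefix)
  ts <- bin_durations(log, "sniff", hours)
  nest <- nest_covariate(log, hours)
  ts |>
    dplyr::left_join(nest, by = c("subject_id", "hour")) |>
    dplyr::mutate(nest_s = dplyr::coalesce(.data$nest_s, 0), group = group)
}

make_two_group_sniff <- function(seed, effect_spec_ko = list(),
                                 n_subjects = 7, hours = 144) {
  dplyr::bind_rows(
    make_sniff_group(seed, "KO", "k", n_subjects, hours, effect_spec_ko),
    make_sniff_group(seed + 100000L, "WT", "w", n_subjects, hours)
  ) |> log_transform()
}

run_injection_delta <- function(seed, mult, first_hours = 9) {
  p <- sim_colony_params(n_subjects = 4, days = 15, seed = seed)
  sim <- simulate_injection_experiment(
    p, effect = list(behavior = "sniff", first_hours = first_hours,
                     multiplier = mult),
    behaviors = "sniff")
  ts <- bin_durations(sim$events, "sniff", 15 * 24)
  d <- baseline_delta(ts, sim$schedule) |>
    dplyr::rename(hour = "hour_post", value = "delta", group = "treatment")
  analyze_contrast(d, k = 10, family = "gaussian")
}
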