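#' Parameters of the mouse colony event-log simulator
#'
#' Emulates the RFID-annotated event stream of a semi-natural colony:
#' `n_subjects` mice observed around the clock for `days` days under a
#' 12:12 photoperiod. Per subject and behavior, events arrive as an
#' inhomogeneous Poisson process whose hourly rate is the base rate,
#' multiplied in dark hours by `dark_intensity_multiplier` and by any
#' matching `effect_spec` window. Event durations are lognormal;
#' `distance_step` events instead carry a lognormal cm magnitude over a
#' fixed sampling interval. Nest occupancy is generated first as an
#' alternating renewal process with phase-dependent mean bout lengths,
#' and (by default) social events starting while the subject is nested
#' are suppressed — this builds the real confound the nest covariate is
#' meant to correct.
#'
#' @param n_subjects colony size (default 4).
#' @param days recording length in days (default 6).
#' @param dark_onset_hour hour-of-day at which the dark phase starts
#'   (default 0: each experimental day begins with its dark phase).
#' @param dark_intensity_multiplier rate factor (>= 1) applied to all
#'   behaviors in dark hours; mice are nocturnal, so the default 2.5
#'   concentrates activity in the dark phase.
#' @param base_event_rate_per_h named light-phase event rates per hour.
#' @param event_duration_meanlog,event_duration_sdlog lognormal duration
#'   parameters for social events, in log seconds.
#' @param distance_magnitude_meanlog,distance_magnitude_sdlog lognormal
#'   parameters of the cm magnitude of one `distance_step`.
#' @param distance_step_interval_s nominal length of one distance
#'   sampling interval, seconds.
#' @param nest_in_mean_s,nest_out_mean_s mean nest-bout and
#'   out-of-nest-bout lengths (seconds), named by phase; the defaults
#'   put subjects in the nest mostly during the light (rest) phase.
#' @param suppress_in_nest drop social/distance events starting while the
#'   subject is in a nest (default `TRUE`).
#' @param effect_spec list of planted effects, each a list with elements
#'   `behavior`, `hours` (0-based experiment hours), `multiplier`, and
#'   optionally `subjects` (default: all subjects).
#' @param seed integer seed; each subject has its own substream.
#' @return a `sim_colony_params` list.
#' @export
sim_colony_params <- function(n_subjects = 4, days = 6, dark_onset_hour = 0,
                              dark_intensity_multiplier = 2.5,
                              base_event_rate_per_h = c(sniff = 10,
                                                        approach = 12,
                                                        distance_step = 60),
                              event_duration_meanlog = log(8),
                              event_duration_sdlog = 0.6,
                              distance_magnitude_meanlog = log(20),
                              distance_magnitude_sdlog = 0.8,
                              distance_step_interval_s = 30,
                              nest_in_mean_s = c(light = 2400, dark = 600),
                              nest_out_mean_s = c(light = 900, dark = 3000),
                              suppress_in_nest = TRUE,
                              effect_spec = list(), seed = 1) {
  if (any(base_event_rate_per_h <= 0) || dark_intensity_multiplier < 1 ||
      days <= 0 || n_subjects < 1) {
    stop_socioscope("colony simulator rates must be positive and the dark multiplier >= 1")
  }
  H <- days * 24
  for (e in effect_spec) {
    if (is.null(e$behavior) || is.null(e$hours) || is.null(e$multiplier)) {
      stop_socioscope("each effect needs behavior, hours and multiplier")
    }
    if (e$multiplier <= 0) stop_socioscope("effect multipliers must be positive")
    if (any(e$hours < 0 | e$hours >= H)) {
      stop_socioscope("effect window outside the %d-hour recording", H)
    }
  }
  structure(
    list(n_subjects = n_subjects, days = days,
         dark_onset_hour = dark_onset_hour,
         dark_intensity_multiplier = dark_intensity_multiplier,
         base_event_rate_per_h = base_event_rate_per_h,
         event_duration_meanlog = event_duration_meanlog,
         event_duration_sdlog = event_duration_sdlog,
         distance_magnitude_meanlog = distance_magnitude_meanlog,
         distance_magnitude_sdlog = distance_magnitude_sdlog,
         distance_step_interval_s = distance_step_interval_s,
         nest_in_mean_s = nest_in_mean_s, nest_out_mean_s = nest_out_mean_s,
         suppress_in_nest = suppress_in_nest,
         effect_spec = effect_spec, seed = seed),
    class = "sim_colony_params"
  )
}

# alternating out/in renewal nest schedule for one subject; returns a
# matrix of [start, stop) nest intervals within [0, T)
simulate_nest_schedule <- function(p, T_s) {
  phase_at <- function(t) {
    hour_phase(floor(t / 3600), p$dark_onset_hour)
  }
  t <- 0
  starts <- c()
  stops <- c()
  while (t < T_s) {
    t <- t + stats::rexp(1, 1 / p$nest_out_mean_s[[phase_at(min(t, T_s - 1))]])
    if (t >= T_s) break
    dur <- stats::rexp(1, 1 / p$nest_in_mean_s[[phase_at(t)]])
    starts <- c(starts, t)
    stops <- c(stops, min(t + dur, T_s))
    t <- t + dur
  }
  cbind(start = starts, stop = stops)
}

in_any_interval <- function(x, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (x >= intervals[i, 1] & x < intervals[i, 2])
  }
  out
}

#' Simulate a colony event log
#'
#' See [sim_colony_params()] for the generative model. Deterministic
#' given the parameter set (including its seed); per-subject substreams
#' mean adding a subject never changes another subject's events.
#'
#' @param p a [sim_colony_params()].
#' @param behaviors behaviors to generate (default: all with a base
#'   rate); restricting this speeds up studies that analyze one behavior.
#' @param subject_prefix prefix of the generated subject ids.
#' @return event-log tibble: `subject_id`, `behavior`, `start_s`,
#'   `stop_s`, `target_id`, `magnitude` (NA except `distance_step`),
#'   including the `in_nest` bouts.
#' @export
#' @examples
#' p <- sim_colony_params(days = 1, seed = 7)
#' log <- simulate_mouse_colony(p)
#' dplyr::count(log, behavior)
simulate_mouse_colony <- function(p, behaviors = NULL, subject_prefix = "m") {
  stopifnot(inherits(p, "sim_colony_params"))
  behaviors <- behaviors %||% names(p$base_event_rate_per_h)
  H <- p$days * 24
  T_s <- H * 3600
  ids <- sprintf("%s%d", subject_prefix, seq_len(p$n_subjects))
  dark <- hour_phase(0:(H - 1), p$dark_onset_hour) == "dark"

  per_subject <- function(i) {
    sid <- ids[i]
    with_seed(substream_seed(p$seed, i), {
      nest <- simulate_nest_schedule(p, T_s)
      evs <- list()
      if (!is.null(nest) && nrow(nest) > 0) {
        evs$nest <- tibble::tibble(
          subject_id = sid, behavior = "in_nest",
          start_s = nest[, 1], stop_s = nest[, 2],
          target_id = NA_character_, magnitude = NA_real_)
      }
      for (b in behaviors) {
        rate <- rep(p$base_event_rate_per_h[[b]], H)
        rate[dark] <- rate[dark] * p$dark_intensity_multiplier
        for (e in p$effect_spec) {
          applies <- is.null(e$subjects) || sid %in% e$subjects
          if (applies && e$behavior == b) {
            rate[e$hours + 1] <- rate[e$hours + 1] * e$multiplier
          }
        }
        counts <- stats::rpois(H, rate)
        n_ev <- sum(counts)
        if (n_ev == 0) next
        start <- rep(0:(H - 1), counts) * 3600 + stats::runif(n_ev) * 3600
        if (b == "distance_step") {
          dur <- rep(p$distance_step_interval_s, n_ev)
          mag <- stats::rlnorm(n_ev, p$distance_magnitude_meanlog,
                               p$distance_magnitude_sdlog)
        } else {
          dur <- stats::rlnorm(n_ev, p$event_duration_meanlog,
                               p$event_duration_sdlog)
          mag <- rep(NA_real_, n_ev)
        }
        tgt <- if (p$n_subjects > 1 && b != "distance_step") {
          # inverse-cdf draw: consumes exactly n_ev uniforms however many
          # conspecifics exist, keeping substreams stable across colony sizes
          others <- setdiff(ids, sid)
          others[pmin(floor(stats::runif(n_ev) * length(others)) + 1,
                      length(others))]
        } else rep(NA_character_, n_ev)
        keep <- if (p$suppress_in_nest) !in_any_interval(start, nest) else
          rep(TRUE, n_ev)
        if (!any(keep)) next
        evs[[b]] <- tibble::tibble(
          subject_id = sid, behavior = b,
          start_s = start[keep],
          stop_s = pmin(start[keep] + dur[keep], T_s),
          target_id = tgt[keep], magnitude = mag[keep])
      }
      dplyr::bind_rows(evs)
    })
  }

  purrr::map(seq_len(p$n_subjects), per_subject) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$start_s, .data$subject_id)
}

#' Simulate a staggered, twin-arena injection experiment
#'
#' Two matched colonies are generated: in the treatment arena each
#' subject is injected in turn (every `injection_every_days` days,
#' starting on day `injection_start_day`, at dark onset) and its own
#' event rates for `effect$behavior` are multiplied by
#' `effect$multiplier` for the first `effect$first_hours` hours after
#' the injection; the twin arena receives vehicle at matched times and
#' no rate change. This mirrors a counterbalanced acute-drug design
#' with a step (non-decaying) drug effect.
#'
#' @param p a [sim_colony_params()]; `p$days` must cover every
#'   injection's 24 h pre and post windows.
#' @param effect list with `behavior`, `first_hours`, `multiplier`.
#' @param injection_start_day first injection day (1-based, default 3).
#' @param injection_every_days spacing between injections (default 3).
#' @param behaviors passed to [simulate_mouse_colony()].
#' @return list with `events` (both arenas; subjects `A_m*` drug,
#'   `B_m*` vehicle) and `schedule` (one row per subject:
#'   `subject_id`, `injection_hour`, `treatment`, `arena_id`,
#'   `twin_arena_id`).
#' @export
simulate_injection_experiment <- function(p,
                                          effect = list(behavior = "sniff",
                                                        first_hours = 9,
                                                        multiplier = 0.4),
                                          injection_start_day = 3,
                                          injection_every_days = 3,
                                          behaviors = NULL) {
  stopifnot(inherits(p, "sim_colony_params"))
  H <- p$days * 24
  inj_hours <- (injection_start_day - 1 +
                  injection_every_days * (seq_len(p$n_subjects) - 1)) * 24 +
    p$dark_onset_hour
  if (inj_hours[1] < 24 || max(inj_hours) + max(24, effect$first_hours) > H) {
    stop_socioscope(
      "horizon too short: need hours [%d, %d] inside a %d-hour recording",
      inj_hours[1] - 24, max(inj_hours) + 24, H)
  }

  drug_effects <- purrr::imap(inj_hours, function(h, j) {
    list(subjects = sprintf("A_m%d", j), behavior = effect$behavior,
         hours = h + 0:(effect$first_hours - 1),
         multiplier = effect$multiplier)
  })
  pA <- p
  pA$effect_spec <- c(p$effect_spec, drug_effects)
  pA$seed <- substream_seed(p$seed, 101)
  pB <- p
  pB$seed <- substream_seed(p$seed, 202)

  events <- dplyr::bind_rows(
    simulate_mouse_colony(pA, behaviors = behaviors, subject_prefix = "A_m"),
    simulate_mouse_colony(pB, behaviors = behaviors, subject_prefix = "B_m")
  )
  schedule <- tibble::tibble(
    subject_id = c(sprintf("A_m%d", seq_len(p$n_subjects)),
                   sprintf("B_m%d", seq_len(p$n_subjects))),
    injection_hour = rep(inj_hours, 2),
    treatment = rep(c("drug", "vehicle"), each = p$n_subjects),
    arena_id = rep(c("A", "B"), each = p$n_subjects),
    twin_arena_id = rep(c("B", "A"), each = p$n_subjects)
  )
  list(events = events, schedule = schedule)
}
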