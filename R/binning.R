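#' Behavior vocabulary for colony event logs
#'
#' The closed set of annotation labels the longitudinal pipeline accepts:
#' directed social behaviors (`sniff`, `approach`), nest occupancy
#' (`in_nest`) and locomotion increments (`distance_step`, whose
#' `magnitude` field carries cm moved during the interval).
#'
#' @export
BEHAVIOR_VOCAB <- c("sniff", "approach", "in_nest", "distance_step")

#' Validate a colony event log
#'
#' @param events data frame with columns `subject_id`, `behavior`,
#'   `start_s`, `stop_s` and optionally `target_id`, `magnitude`.
#' @return the log as a tibble, invisibly checked: half-open `[start_s,
#'   stop_s)` spans with `stop_s > start_s >= 0`, behaviors from
#'   [BEHAVIOR_VOCAB].
#' @export
validate_events <- function(events) {
  events <- tibble::as_tibble(events)
  need <- c("subject_id", "behavior", "start_s", "stop_s")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0) {
    stop_socioscope("event log lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(events$behavior), BEHAVIOR_VOCAB)
  if (length(bad) > 0) {
    stop_socioscope("unknown behavior label(s): %s", paste(bad, collapse = ", "))
  }
  if (any(events$start_s < 0)) stop_socioscope("negative event start times")
  if (any(events$stop_s <= events$start_s)) {
    stop_socioscope("events must have stop_s > start_s")
  }
  events
}

#' Light/dark phase of an experiment hour
#'
#' The colony lives under a 12:12 photoperiod; the phase of an hour
#' depends only on `hour %% 24` and the configured dark onset. The
#' default places the dark (active) phase at hours 0-11 of each
#' experimental day, matching designs in which animals enter the arena
#' (or are injected) just before dark onset.
#'
#' @param hour integer hour(s) since experiment start.
#' @param dark_onset_hour hour-of-day (0-23) at which the dark phase
#'   begins.
#' @return character vector, `"dark"` or `"light"`.
#' @export
hour_phase <- function(hour, dark_onset_hour = 0) {
  ifelse(((hour - dark_onset_hour) %% 24) < 12, "dark", "light")
}

# Exact apportioning of half-open event spans onto 1-h bins.  Returns one
# row per (event, hour) with the seconds of overlap; distance_step rows
# instead carry the magnitude share proportional to time overlap.
apportion_hours <- function(events, hours) {
  if (nrow(events) == 0) {
    return(tibble::tibble(row = integer(), hour = integer(), value = double()))
  }
  if (any(events$stop_s > 3600 * hours)) {
    stop_socioscope("event(s) extend beyond the %d-hour recording", hours)
  }
  h0 <- floor(events$start_s / 3600)
  h1 <- ceiling(events$stop_s / 3600) - 1
  nh <- as.integer(h1 - h0 + 1)
  row <- rep(seq_len(nrow(events)), nh)
  hour <- as.integer(sequence(nh) - 1 + rep(h0, nh))
  ovl <- pmin(events$stop_s[row], (hour + 1) * 3600) -
    pmax(events$start_s[row], hour * 3600)
  value <- if ("magnitude" %in% names(events) &&
               any(events$behavior == "distance_step")) {
    len <- events$stop_s - events$start_s
    ifelse(events$behavior[row] == "distance_step",
           events$magnitude[row] * ovl / len[row], ovl)
  } else {
    ovl
  }
  tibble::tibble(row = row, hour = hour, value = value)
}

#' Bin a colony event log into hourly per-subject time series
#'
#' Each event's duration (or, for `distance_step`, its cm magnitude) is
#' apportioned to 1-hour bins by exact overlap, so binning conserves the
#' total exactly; social behaviors are aggregated over all conspecific
#' targets. The result is a dense tibble: every subject appears in every
#' hour, with zeros where nothing happened.
#'
#' @param events a colony event log (see [validate_events()]).
#' @param behavior one label from [BEHAVIOR_VOCAB].
#' @param hours recording length H in hours; bins are `0..H-1`.
#' @param subjects subjects to report (defaults to those in the log);
#'   keeps all-zero subjects in the grid.
#' @param direction `"given"` keys events on the acting subject,
#'   `"received"` re-keys them on `target_id` (passive social behavior).
#' @param dark_onset_hour passed to [hour_phase()].
#' @return tibble with columns `subject_id`, `behavior`, `hour`, `value`
#'   (seconds, or cm for `distance_step`), `day` (1-based), `phase`.
#' @export
#' @examples
#' log <- tibble::tibble(subject_id = "m1", behavior = "sniff",
#'                       start_s = 3500, stop_s = 3700, target_id = "m2")
#' bin_durations(log, "sniff", hours = 2)
bin_durations <- function(events, behavior, hours,
                          subjects = NULL, direction = c("given", "received"),
                          dark_onset_hour = 0) {
  direction <- match.arg(direction)
  events <- validate_events(events)
  ev <- dplyr::filter(events, .data$behavior == !!behavior)
  if (direction == "received") {
    if (!"target_id" %in% names(ev)) {
      stop_socioscope("received-direction binning needs a target_id column")
    }
    ev <- ev |>
      dplyr::filter(!is.na(.data$target_id)) |>
      dplyr::mutate(subject_id = .data$target_id)
  }
  subjects <- subjects %||% sort(unique(ev$subject_id))
  parts <- apportion_hours(ev, hours)
  binned <- tibble::tibble(subject_id = ev$subject_id[parts$row],
                           hour = parts$hour, value = parts$value) |>
    dplyr::group_by(.data$subject_id, .data$hour) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  tidyr::expand_grid(subject_id = subjects, hour = 0:(hours - 1)) |>
    dplyr::left_join(binned, by = c("subject_id", "hour")) |>
    dplyr::mutate(
      behavior = behavior,
      value = dplyr::coalesce(.data$value, 0),
      day = .data$hour %/% 24 + 1L,
      phase = hour_phase(.data$hour, dark_onset_hour)
    ) |>
    dplyr::select("subject_id", "behavior", "hour", "value", "day", "phase")
}

#' Log-transform an hourly behavior series
#'
#' Hourly cumulative durations are right-skewed with exact zeros; the
#' series is modeled on the scale `log(value + offset)`. The default
#' offset of 1 s is negligible against typical hourly totals and makes
#' the zero bins finite. The offset is recorded as attribute
#' `"log_offset"` so the transform is invertible.
#'
#' @param ts a binned series from [bin_durations()].
#' @param offset additive offset, in the units of `value`; must be
#'   positive when zeros are present.
#' @return `ts` with `value` replaced by `log(value + offset)`.
#' @export
log_transform <- function(ts, offset = 1) {
  if (offset < 0) stop_socioscope("offset must be non-negative")
  if (offset == 0 && any(ts$value <= 0)) {
    stop_socioscope("zero values present: use a positive offset")
  }
  out <- dplyr::mutate(ts, value = log(.data$value + offset))
  attr(out, "log_offset") <- offset
  out
}

#' Hourly nest-occupancy covariate
#'
#' Seconds each subject spent inside a nest per hour, used as a covariate
#' because social behavior cannot be observed while the subject is
#' nested. Overlapping nest bouts for one subject are merged (with a
#' warning) before binning, so no bin can exceed 3600 s.
#'
#' @param events a colony event log containing `in_nest` records.
#' @inheritParams bin_durations
#' @return tibble `subject_id`, `hour`, `nest_s`.
#' @export
nest_covariate <- function(events, hours, subjects = NULL,
                           dark_onset_hour = 0) {
  events <- validate_events(events)
  subjects <- subjects %||% sort(unique(events$subject_id))
  nest <- dplyr::filter(events, .data$behavior == "in_nest")
  merged <- nest |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$start_s)
      if (nrow(d) < 2) return(d)
      start <- d$start_s[1]
      stop <- d$stop_s[1]
      out <- list()
      overlapped <- FALSE
      for (i in 2:nrow(d)) {
        if (d$start_s[i] < stop) {
          overlapped <- TRUE
          stop <- max(stop, d$stop_s[i])
        } else {
          out[[length(out) + 1]] <- c(start, stop)
          start <- d$start_s[i]
          stop <- d$stop_s[i]
        }
      }
      out[[length(out) + 1]] <- c(start, stop)
      if (overlapped) {
        rlang::warn(sprintf("merged overlapping in_nest events for %s",
                            key$subject_id[1]))
      }
      m <- do.call(rbind, out)
      tibble::tibble(behavior = "in_nest", start_s = m[, 1], stop_s = m[, 2])
    }) |>
    dplyr::ungroup()
  bin_durations(merged, "in_nest", hours, subjects = subjects,
                dark_onset_hour = dark_onset_hour) |>
    dplyr::select("subject_id", "hour", nest_s = "value")
}

#' Hour-matched baseline subtraction for injection designs
#'
#' For each injected subject, the 24 hourly values preceding the
#' injection are subtracted from the 24 hourly values following it,
#' hour-for-hour: `delta(h) = value(inj + h) - value(inj - 24 + h)` for
#' `h = 0..23`. Because the photoperiod is 24 h, matched hours share a
#' phase, so the delta removes each subject's circadian baseline.
#'
#' @param ts binned (or transformed) series from [bin_durations()].
#' @param schedule injection schedule tibble: `subject_id`,
#'   `injection_hour`, `treatment`, and optionally arena labels.
#' @return tibble `subject_id`, `behavior`, `treatment`, `hour_post`
#'   (0-23), `delta`.
#' @export
baseline_delta <- function(ts, schedule) {
  H <- max(ts$hour) + 1L
  if (anyDuplicated(schedule$subject_id) > 0) {
    stop_socioscope("one injection per subject: duplicated subject_id")
  }
  purrr::pmap(
    dplyr::select(schedule, "subject_id", "injection_hour", "treatment"),
    function(subject_id, injection_hour, treatment) {
      if (injection_hour < 24 || injection_hour > H - 24) {
        stop_socioscope(
          "injection at hour %d lacks 24 h of pre/post coverage (H = %d)",
          injection_hour, H)
      }
      s <- dplyr::filter(ts, .data$subject_id == !!subject_id)
      if (nrow(s) == 0) {
        stop_socioscope("subject %s absent from the series", subject_id)
      }
      s |>
        dplyr::group_by(.data$behavior) |>
        dplyr::reframe(
          hour_post = 0:23,
          delta = .data$value[match(injection_hour + 0:23, .data$hour)] -
            .data$value[match(injection_hour - 24 + 0:23, .data$hour)]
        ) |>
        dplyr::mutate(subject_id = subject_id, treatment = treatment,
                      .before = 1)
    }
  ) |>
    dplyr::bind_rows()
}
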