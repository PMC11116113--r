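#' Synthetic two-fly configuration held fixed for a whole recording
#'
#' Places a stationary actor at the arena center and a stationary target
#' at a controlled relative bearing and distance, for a controlled number
#' of frames. Used to probe the detector's decision boundaries one
#' condition at a time.
#'
#' @param rel_angle_deg bearing of the target relative to the actor's
#'   body axis, in degrees.
#' @param dist_bl center-to-center distance in actor body lengths.
#' @param duration_s length of the recording in seconds.
#' @param frame_rate_hz frame rate in Hz.
#' @param body_length_mm body length of both flies in mm.
#' @return a two-individual `trackset`.
#' @export
two_fly_configuration <- function(rel_angle_deg, dist_bl, duration_s,
                                  frame_rate_hz = 30, body_length_mm = 2.5) {
  a <- arena_config(frame_rate_hz = frame_rate_hz)
  n <- round(duration_s * frame_rate_hz)
  if (n < 1) stop_socioscope("duration too short for one frame")
  cx <- a$width_mm / 2
  cy <- a$height_mm / 2
  d <- dist_bl * body_length_mm
  theta <- rel_angle_deg * pi / 180
  df <- data.frame(
    id = rep(c("actor", "target"), each = n),
    frame = rep(seq_len(n) - 1L, 2),
    # actor heads +x; target sits at bearing `theta` from that axis
    x = rep(c(cx, cx + d * cos(theta)), each = n),
    y = rep(c(cy, cy + d * sin(theta)), each = n),
    heading = rep(c(0, pi), each = n)
  )
  as_trackset(df, a, body_length_mm = body_length_mm)
}

emits_event <- function(rel_angle_deg, dist_bl, duration_s, frame_rate_hz,
                        params) {
  ts <- two_fly_configuration(rel_angle_deg, dist_bl, duration_s,
                              frame_rate_hz)
  ev <- detect_interactions(ts, params)
  sum(ev$actor_id == "actor") > 0
}

#' Recover the detector's decision boundaries from synthetic probes
#'
#' Each function scans or bisects a one-parameter family of
#' [two_fly_configuration()] recordings and reports where the detector
#' switches between emitting and not emitting an interaction. They treat
#' the detector as a black box, so the recovered boundary is evidence of
#' the implemented thresholds, not a restatement of the configuration.
#'
#' @param params a [detector_params()] under test.
#' @param frame_rate_hz probe frame rate.
#' @param tol bisection tolerance in degrees (angle) or body lengths
#'   (distance).
#' @return `recover_angle_threshold()`: the supremum relative bearing (in
#'   degrees) still emitting an interaction, to within `tol`.
#' @export
recover_angle_threshold <- function(params = detector_params(),
                                    frame_rate_hz = 30, tol = 1e-6) {
  # held 1 BL apart for 3 s: distance and duration are safely sub/supra-
  # threshold, so only the orientation condition moves
  lo <- 0
  hi <- 180
  stopifnot(emits_event(lo, 1, 3, frame_rate_hz, params),
            !emits_event(hi, 1, 3, frame_rate_hz, params))
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (emits_event(mid, 1, 3, frame_rate_hz, params)) lo <- mid else hi <- mid
    it <- it + 1L
  }
  structure((lo + hi) / 2, iterations = it)
}

#' @rdname recover_angle_threshold
#' @return `recover_distance_threshold()`: the supremum distance (in body
#'   lengths) still emitting an interaction, to within `tol`.
#' @export
recover_distance_threshold <- function(params = detector_params(),
                                       frame_rate_hz = 30, tol = 1e-6) {
  lo <- 0.5
  hi <- 8
  stopifnot(emits_event(0, lo, 3, frame_rate_hz, params),
            !emits_event(0, hi, 3, frame_rate_hz, params))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (emits_event(0, mid, 3, frame_rate_hz, params)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @rdname recover_angle_threshold
#' @param lengths_s episode lengths to scan, in seconds. The default grid
#'   steps by 0.1 s, which is exactly representable at the default 10 Hz
#'   probe rate so no length is rounded.
#' @return `recover_duration_threshold()`: the smallest scanned episode
#'   length producing exactly one detected event (seconds); `NA` if none
#'   does.
#' @export
recover_duration_threshold <- function(params = detector_params(),
                                       frame_rate_hz = 10,
                                       lengths_s = seq(0.1, 3.0, by = 0.1)) {
  for (L in sort(lengths_s)) {
    ts <- two_fly_configuration(0, 1, L, frame_rate_hz)
    if (sum(detect_interactions(ts, params)$actor_id == "actor") == 1) {
      return(L)
    }
  }
  NA_real_
}
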