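#' Detector thresholds for the three-condition interaction definition
#'
#' A directed social interaction between an actor and a target requires,
#' simultaneously: (1) the angle between the actor's body axis and the
#' vector to the target's center strictly below `max_angle_deg`;
#' (2) center-to-center distance at most `max_dist_bl` body lengths;
#' (3) both conditions maintained for at least `min_duration_s`.
#' The defaults (90 degrees, 2 body lengths, 1.5 s) are the standard
#' thresholds of the fly proximity-interaction assay; an episode passing
#' them is the walking-fly analogue of a mouse sniffing bout.
#'
#' @param max_angle_deg angular threshold in degrees, in `(0, 180]`;
#'   comparison is strict (`<`).
#' @param max_dist_bl distance threshold in body lengths; comparison is
#'   inclusive (`<=`).
#' @param min_duration_s minimum maintained duration in seconds;
#'   comparison is inclusive (`>=`). Durations are frame counts divided by
#'   the frame rate, without sub-frame interpolation.
#' @param gap_tolerance_frames number of consecutive predicate-false or
#'   tracking-gap frames a run may bridge. The default 0 is the
#'   conservative reading: a single bad frame splits a run.
#' @param body_length_mode `"actor"` scales the distance threshold by the
#'   actor's body length; `"mean_pair"` by the mean of the pair.
#' @param mutual if `TRUE`, a frame qualifies only when the predicate
#'   holds in both directions simultaneously, and each unordered pair is
#'   reported once.
#' @return a `detector_params` list.
#' @export
detector_params <- function(max_angle_deg = 90, max_dist_bl = 2,
                            min_duration_s = 1.5, gap_tolerance_frames = 0L,
                            body_length_mode = c("actor", "mean_pair"),
                            mutual = FALSE) {
  body_length_mode <- match.arg(body_length_mode)
  if (!(max_angle_deg > 0 && max_angle_deg <= 180)) {
    stop_socioscope("`max_angle_deg` must lie in (0, 180]")
  }
  if (max_dist_bl <= 0) stop_socioscope("`max_dist_bl` must be positive")
  if (min_duration_s < 0) stop_socioscope("`min_duration_s` must be >= 0")
  if (gap_tolerance_frames < 0 || gap_tolerance_frames %% 1 != 0) {
    stop_socioscope("`gap_tolerance_frames` must be a non-negative integer")
  }
  structure(
    list(max_angle_deg = max_angle_deg, max_dist_bl = max_dist_bl,
         min_duration_s = min_duration_s,
         gap_tolerance_frames = as.integer(gap_tolerance_frames),
         body_length_mode = body_length_mode, mutual = mutual),
    class = "detector_params"
  )
}

# Columns of one individual as aligned vectors over the common frame domain.
track_vectors <- function(ts, id) {
  rows <- ts$individual_id == id
  if (!any(rows)) stop_socioscope("unknown individual id: %s", id)
  list(x = ts$x_mm[rows][order(ts$frame[rows])],
       y = ts$y_mm[rows][order(ts$frame[rows])],
       h = ts$heading_rad[rows][order(ts$frame[rows])],
       valid = ts$valid[rows][order(ts$frame[rows])],
       bl = ts$body_length_mm[rows][1])
}

# Vectorized geometric predicate for one directed pair; NA where either
# individual is untracked.
pair_predicate <- function(a, b, params) {
  bearing <- atan2(b$y - a$y, b$x - a$x)
  ang_ok <- angle_diff(a$h, bearing) < params$max_angle_deg * pi / 180
  bl <- switch(params$body_length_mode,
               actor = a$bl,
               mean_pair = (a$bl + b$bl) / 2)
  dist_ok <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2) <= params$max_dist_bl * bl
  ok <- ang_ok & dist_ok
  ok[!(a$valid & b$valid)] <- NA
  ok
}

#' Evaluate the geometric interaction predicate at given frames
#'
#' The per-frame conjunction of the orientation and proximity conditions,
#' directed from `actor` to `target`. The predicate is asymmetric: the
#' orientation condition uses the actor's heading only.
#'
#' @param ts a `trackset`.
#' @param actor,target individual ids.
#' @param frame integer frame index (0-based); may be a vector.
#' @param params a [detector_params()].
#' @return logical vector, one element per frame; `NA` where either
#'   individual is untracked on that frame.
#' @export
frame_predicate <- function(ts, actor, target, frame,
                            params = detector_params()) {
  if (actor == target) stop_socioscope("actor and target must differ")
  a <- track_vectors(ts, actor)
  b <- track_vectors(ts, target)
  n <- length(a$x)
  if (any(frame < 0 | frame >= n)) {
    stop_socioscope("frame outside the recording domain [0, %d)", n)
  }
  idx <- frame + 1L
  ok <- pair_predicate(
    list(x = a$x[idx], y = a$y[idx], h = a$h[idx], valid = a$valid[idx], bl = a$bl),
    list(x = b$x[idx], y = b$y[idx], h = b$h[idx], valid = b$valid[idx], bl = b$bl),
    params
  )
  if (params$mutual) {
    ok2 <- pair_predicate(
      list(x = b$x[idx], y = b$y[idx], h = b$h[idx], valid = b$valid[idx], bl = b$bl),
      list(x = a$x[idx], y = a$y[idx], h = a$h[idx], valid = a$valid[idx], bl = a$bl),
      params
    )
    ok <- ok & ok2
  }
  ok
}

# Maximal runs of TRUE in `ok` (NA/FALSE both break runs), merging runs
# separated by gaps of at most `gap_tol` frames.  Returns half-open
# [start, end) 0-based frame spans.
predicate_runs <- function(ok, gap_tol = 0L) {
  ok <- !is.na(ok) & ok
  if (!any(ok)) return(data.frame(start = integer(), end = integer()))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  if (gap_tol > 0L && nrow(runs) > 1L) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] <= gap_tol) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs
}

#' Detect directed social interactions in a trackset
#'
#' For every ordered pair of individuals, maximal runs of frames on which
#' [frame_predicate()] holds (optionally bridging short gaps) are emitted
#' as interaction events when their duration reaches the threshold.
#'
#' @inheritParams frame_predicate
#' @return a tibble with one row per event: `actor_id`, `target_id`,
#'   `start_frame`, `end_frame` (half-open), `duration_s`, sorted by
#'   `(start_frame, actor_id, target_id)`. With `mutual = TRUE` each
#'   unordered pair appears once, with the lexicographically smaller id
#'   as actor.
#' @export
#' @examples
#' ts <- simulate_fly_arena(sim_fly_params(duration_s = 30, seed = 1))
#' detect_interactions(ts)
detect_interactions <- function(ts, params = detector_params()) {
  a <- arena(ts)
  if (is.null(a$frame_rate_hz) || !is.finite(a$frame_rate_hz)) {
    stop_socioscope("frame rate missing from arena configuration")
  }
  ids <- sort(unique(ts$individual_id))
  tv <- lapply(stats::setNames(ids, ids), function(i) track_vectors(ts, i))
  pairs <- expand.grid(actor = ids, target = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$actor != pairs$target, ]
  if (params$mutual) pairs <- pairs[pairs$actor < pairs$target, ]

  res <- purrr::pmap(pairs, function(actor, target) {
    ok <- pair_predicate(tv[[actor]], tv[[target]], params)
    if (params$mutual) {
      ok <- ok & pair_predicate(tv[[target]], tv[[actor]], params)
    }
    runs <- predicate_runs(ok, params$gap_tolerance_frames)
    dur <- (runs$end - runs$start) / a$frame_rate_hz
    keep <- dur >= params$min_duration_s
    tibble::tibble(actor_id = actor, target_id = target,
                   start_frame = runs$start[keep], end_frame = runs$end[keep],
                   duration_s = dur[keep])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(actor_id = character(), target_id = character(),
                          start_frame = integer(), end_frame = integer(),
                          duration_s = double()))
  }
  dplyr::arrange(out, .data$start_frame, .data$actor_id, .data$target_id)
}

#' Per-individual locomotor and social summaries
#'
#' Path length and speed are computed over valid consecutive-frame steps
#' only; a step that spans a tracking gap is excluded so that re-entry
#' jumps cannot inflate speed.
#'
#' @param ts a `trackset`.
#' @param events event tibble from [detect_interactions()] on `ts`.
#' @return tibble with one row per individual: interaction count and mean
#'   duration as actor, total distance (mm and cm) and mean speed (mm/s).
#' @export
summarize_individuals <- function(ts, events = detect_interactions(ts)) {
  a <- arena(ts)
  ids <- sort(unique(ts$individual_id))
  loco <- purrr::map(stats::setNames(ids, ids), function(i) {
    v <- track_vectors(ts, i)
    step_ok <- v$valid[-length(v$valid)] & v$valid[-1]
    d <- sqrt(diff(v$x)^2 + diff(v$y)^2)[step_ok]
    tdist <- sum(d)
    tsec <- sum(step_ok) / a$frame_rate_hz
    tibble::tibble(total_distance_mm = tdist,
                   mean_speed_mm_s = if (tsec > 0) tdist / tsec else 0)
  }) |>
    dplyr::bind_rows(.id = "individual_id")
  soc <- events |>
    dplyr::group_by(individual_id = .data$actor_id) |>
    dplyr::summarise(n_interactions = dplyr::n(),
                     mean_duration_s = mean(.data$duration_s),
                     .groups = "drop")
  loco |>
    dplyr::left_join(soc, by = "individual_id") |>
    dplyr::mutate(
      n_interactions = dplyr::coalesce(.data$n_interactions, 0L),
      total_distance_cm = .data$total_distance_mm / 10
    ) |>
    dplyr::select("individual_id", "n_interactions", "mean_duration_s",
                  "total_distance_mm", "total_distance_cm", "mean_speed_mm_s")
}

#' Arena-level summary of one recording
#'
#' The arena (one group of animals over one recording) is the unit of
#' analysis: interaction counts are summed over all ordered pairs, the
#' mean event duration is taken over all events, distance is summed over
#' individuals and speed averaged over individuals.
#'
#' @inheritParams summarize_individuals
#' @return a one-row tibble (`n_interactions`, `mean_duration_s` —
#'   `NA` when there are no events —, `total_distance_mm`,
#'   `total_distance_cm`, `mean_speed_mm_s`) plus any `group_meta`
#'   labels of the trackset as extra columns. The per-individual
#'   breakdown is attached as attribute `"per_individual"`.
#' @export
summarize_group <- function(ts, events = detect_interactions(ts)) {
  ind <- summarize_individuals(ts, events)
  out <- tibble::tibble(
    n_interactions = nrow(events),
    mean_duration_s = if (nrow(events) > 0) mean(events$duration_s) else NA_real_,
    total_distance_mm = sum(ind$total_distance_mm),
    total_distance_cm = sum(ind$total_distance_mm) / 10,
    mean_speed_mm_s = mean(ind$mean_speed_mm_s)
  )
  meta <- group_meta(ts)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  attr(out, "per_individual") <- ind
  out
}
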