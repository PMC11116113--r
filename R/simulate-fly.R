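# run expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rtruncnorm0 <- function(n, mean, sd) {
  if (mean == 0 && sd == 0) return(numeric(n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Parameters of the fly arena simulator
#'
#' The generator emulates the walking-fly group assay: `n_flies`
#' individuals in a rectangular arena, observed for `duration_s` seconds.
#' Movement is a correlated random walk: each frame the heading turns by
#' a wrapped-normal angle (spread set by `heading_persistence`, the
#' inverse variance of the turn in rad^-2) plus a pull of weight
#' `attraction_strength` toward the nearest neighbour; speed is drawn
#' from a normal truncated at zero; walls reflect specularly.
#'
#' @param n_flies number of flies (default 4, the assay group size).
#' @param duration_s recording length in seconds (default 600, the 10-min
#'   assay).
#' @param frame_rate_hz frame rate (default 30).
#' @param mean_speed_mm_s,speed_sd_mm_s walking-speed distribution in
#'   mm/s before truncation at 0; a mean of exactly 0 gives stationary
#'   flies (a degenerate control, not a truncated normal).
#' @param heading_persistence concentration of the turning distribution:
#'   per-frame turns are wrapped normal with sd
#'   `1/sqrt(heading_persistence)` rad.
#' @param attraction_strength social-attraction weight, `>= 0`. The
#'   heading relaxes toward the bearing of the nearest neighbour at rate
#'   `attraction_strength * 4.5` per second of bearing error (capped at
#'   full reorientation per frame): flies turn at a finite angular
#'   velocity, so even strong attraction produces pursuit bouts rather
#'   than an instantaneous heading lock. 0 is a plain correlated random
#'   walk.
#' @param body_length_mm body length assigned to every fly.
#' @param collision_radius_mm hard-core exclusion distance: overlapping
#'   flies are pushed apart to this center-to-center separation each
#'   frame (bodies cannot occupy the same spot). Defaults to one body
#'   length; 0 disables exclusion.
#' @param arena an [arena_config()]; its frame rate is overridden by
#'   `frame_rate_hz`.
#' @param seed integer seed; each fly draws from its own counter-based
#'   substream, so adding a fly never perturbs the others' trajectories.
#' @return a `sim_fly_params` list.
#' @export
sim_fly_params <- function(n_flies = 4, duration_s = 600, frame_rate_hz = 30,
                           mean_speed_mm_s = 8, speed_sd_mm_s = 4,
                           heading_persistence = 10, attraction_strength = 0.3,
                           body_length_mm = 2.5, collision_radius_mm = NULL,
                           arena = NULL, seed = 1) {
  if (attraction_strength < 0) stop_socioscope("attraction_strength must be >= 0")
  if (n_flies < 1 || duration_s <= 0 || frame_rate_hz <= 0 ||
      body_length_mm <= 0 || heading_persistence <= 0) {
    stop_socioscope("fly simulator rates and lengths must be positive")
  }
  arena <- arena %||% arena_config(frame_rate_hz = frame_rate_hz)
  arena$frame_rate_hz <- frame_rate_hz
  structure(
    list(n_flies = n_flies, duration_s = duration_s,
         frame_rate_hz = frame_rate_hz, mean_speed_mm_s = mean_speed_mm_s,
         speed_sd_mm_s = speed_sd_mm_s,
         heading_persistence = heading_persistence,
         attraction_strength = attraction_strength,
         body_length_mm = body_length_mm,
         collision_radius_mm = collision_radius_mm %||% body_length_mm,
         arena = arena, seed = seed),
    class = "sim_fly_params"
  )
}

#' Simulate a fly arena recording
#'
#' Correlated random walk with nearest-neighbour attraction and specular
#' wall reflection (see [sim_fly_params()]); bit-reproducible given the
#' parameter set.
#'
#' @param p a [sim_fly_params()].
#' @return a `trackset` with `n_flies` fully valid tracks.
#' @export
#' @examples
#' ts <- simulate_fly_arena(sim_fly_params(duration_s = 20, seed = 42))
#' summarize_group(ts)
simulate_fly_arena <- function(p) {
  stopifnot(inherits(p, "sim_fly_params"))
  a <- p$arena
  N <- round(p$duration_s * p$frame_rate_hz)
  n <- p$n_flies
  turn_sd <- 1 / sqrt(p$heading_persistence)

  # per-fly substreams: noise sequences and initial state drawn
  # independently of the number of flies simulated
  eps <- matrix(0, N, n)
  spd <- matrix(0, N, n)
  x0 <- y0 <- h0 <- numeric(n)
  margin <- 5
  for (i in seq_len(n)) {
    with_seed(substream_seed(p$seed, i), {
      eps[, i] <- stats::rnorm(N, 0, turn_sd)
      spd[, i] <- rtruncnorm0(N, p$mean_speed_mm_s, p$speed_sd_mm_s)
      x0[i] <- stats::runif(1, margin, a$width_mm - margin)
      y0[i] <- stats::runif(1, margin, a$height_mm - margin)
      h0[i] <- stats::runif(1, -pi, pi)
    })
  }

  dt <- 1 / p$frame_rate_hz
  X <- matrix(0, N, n)
  Y <- matrix(0, N, n)
  H <- matrix(0, N, n)
  x <- x0
  y <- y0
  h <- h0
  for (t in seq_len(N)) {
    if (n > 1 && p$attraction_strength > 0) {
      dx <- outer(x, x, function(a_, b_) b_ - a_)
      dy <- outer(y, y, function(a_, b_) b_ - a_)
      d2 <- dx^2 + dy^2
      diag(d2) <- Inf
      nn <- max.col(-d2, ties.method = "first")
      bearing <- atan2(dy[cbind(seq_len(n), nn)], dx[cbind(seq_len(n), nn)])
      pull <- min(1, p$attraction_strength * 4.5 / p$frame_rate_hz)
      h <- h + pull * wrap_angle(bearing - h)
    }
    h <- wrap_angle(h + eps[t, ])
    x <- x + spd[t, ] * dt * cos(h)
    y <- y + spd[t, ] * dt * sin(h)
    # specular reflection at the four walls
    ref <- x < 0
    x[ref] <- -x[ref]
    h[ref] <- wrap_angle(pi - h[ref])
    ref <- x > a$width_mm
    x[ref] <- 2 * a$width_mm - x[ref]
    h[ref] <- wrap_angle(pi - h[ref])
    ref <- y < 0
    y[ref] <- -y[ref]
    h[ref] <- -h[ref]
    ref <- y > a$height_mm
    y[ref] <- 2 * a$height_mm - y[ref]
    h[ref] <- -h[ref]
    x <- pmin(pmax(x, 0), a$width_mm)
    y <- pmin(pmax(y, 0), a$height_mm)
    # hard-core exclusion: overlapping bodies are pushed apart
    r0 <- p$collision_radius_mm
    if (n > 1 && r0 > 0) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          ddx <- x[j] - x[i]
          ddy <- y[j] - y[i]
          d <- sqrt(ddx^2 + ddy^2)
          if (d < r0) {
            ux <- if (d > 1e-9) ddx / d else cos(h[i])
            uy <- if (d > 1e-9) ddy / d else sin(h[i])
            push <- (r0 - d) / 2
            x[i] <- x[i] - ux * push
            y[i] <- y[i] - uy * push
            x[j] <- x[j] + ux * push
            y[j] <- y[j] + uy * push
          }
        }
      }
      x <- pmin(pmax(x, 0), a$width_mm)
      y <- pmin(pmax(y, 0), a$height_mm)
    }
    X[t, ] <- x
    Y[t, ] <- y
    H[t, ] <- h
  }

  ids <- sprintf("fly_%d", seq_len(n))
  df <- data.frame(
    id = rep(ids, each = N),
    frame = rep(seq_len(N) - 1L, n),
    x = as.vector(X), y = as.vector(Y), heading = as.vector(H)
  )
  as_trackset(df, a, body_length_mm = p$body_length_mm,
              group_meta = list(simulated = TRUE, seed = p$seed))
}

#' Overwrite a trackset with known ground-truth interaction episodes
#'
#' For each requested episode the actor/target pair is frozen into a
#' canonical interacting pose (one body length apart, actor facing the
#' target, target facing away) for exactly the requested frame span, and
#' pushed far apart for a short buffer on each side so the episode cannot
#' merge with surrounding geometry. The detector must then recover
#' exactly the planted episodes whose duration clears the threshold.
#'
#' @param ts a `trackset`.
#' @param episodes data frame with columns `actor`, `target`, `start_s`,
#'   `duration_s`; episodes must not overlap per ordered pair.
#' @param buffer_s seconds of separation enforced on each side.
#' @return the modified `trackset`.
#' @export
plant_interaction_episodes <- function(ts, episodes, buffer_s = 0.3) {
  a <- arena(ts)
  fps <- a$frame_rate_hz
  N <- max(ts$frame) + 1L
  episodes <- tibble::as_tibble(episodes)
  key <- paste(episodes$actor, episodes$target)
  for (kk in unique(key)) {
    e <- episodes[key == kk, ]
    e <- e[order(e$start_s), ]
    if (nrow(e) > 1 &&
        any(e$start_s[-1] < (e$start_s + e$duration_s)[-nrow(e)])) {
      stop_socioscope("overlapping episodes for ordered pair %s", kk)
    }
  }
  set_pose <- function(ts, id, frames, x, y, h) {
    rows <- ts$individual_id == id & ts$frame %in% frames
    ts$x_mm[rows] <- x
    ts$y_mm[rows] <- y
    ts$heading_rad[rows] <- h
    ts$valid[rows] <- TRUE
    ts
  }
  nb <- max(1L, round(buffer_s * fps))
  for (i in seq_len(nrow(episodes))) {
    ep <- episodes[i, ]
    f0 <- round(ep$start_s * fps)
    f1 <- f0 + round(ep$duration_s * fps)   # half-open [f0, f1)
    if (f0 < 0 || f1 > N) {
      stop_socioscope("episode %d lies outside the recording", i)
    }
    bl <- ts$body_length_mm[ts$individual_id == ep$actor][1]
    cx <- a$width_mm / 3
    cy <- a$height_mm / 2
    span <- f0:(f1 - 1)
    ts <- set_pose(ts, ep$actor, span, cx, cy, 0)
    ts <- set_pose(ts, ep$target, span, cx + bl, cy, 0)
    pre <- setdiff(max(0, f0 - nb):(f0 - 1), span)
    post <- setdiff(f1:min(N - 1, f1 + nb - 1), span)
    for (fr in list(pre, post)) {
      fr <- fr[fr >= 0 & fr < N]
      if (length(fr) > 0) {
        ts <- set_pose(ts, ep$actor, fr, 5, 5, pi)
        ts <- set_pose(ts, ep$target, fr, a$width_mm - 5, a$height_mm - 5, 0)
      }
    }
  }
  ts
}
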