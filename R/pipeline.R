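provenance <- function(cfg, seed) {
  list(
    package = "socioscope",
    version = as.character(utils::packageVersion("socioscope")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(cfg)
  )
}

write_provenance <- function(cfg, seed, out_dir) {
  jsonlite::write_json(provenance(cfg, seed),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

read_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) {
    if (!file.exists(cfg)) stop_socioscope("config file not found: %s", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  if (!is.list(cfg)) stop_socioscope("config must be a list or a YAML path")
  cfg
}

require_keys <- function(cfg, keys, where) {
  missing_keys <- setdiff(keys, names(cfg))
  if (length(missing_keys) > 0) {
    stop_socioscope("%s config missing key(s): %s", where,
                    paste(missing_keys, collapse = ", "))
  }
}

#' Run the fly analysis end to end
#'
#' Composes ingestion, interaction detection and arena-level statistics:
#' every configured arena recording (a trajectory table, or a simulation
#' block) is detected and summarized, then each requested response is
#' modeled with [fit_group_model()]. All outputs are written as tidy CSV
#' plus a provenance JSON (parameter hash, seed, package version);
#' identical config and seed reproduce identical numbers.
#'
#' @param cfg a list or YAML path. Required keys: `out_dir`; either
#'   `tracks` (data frame / list of entries with `path`, `sex`,
#'   `genotype`) or `sim` (list of entries with `sex`, `genotype`,
#'   optional [sim_fly_params()] overrides, `n_arenas`). Optional:
#'   `arena` (list of [arena_config()] fields), `detector` (list of
#'   [detector_params()] fields), `responses` (default all three).
#' @param seed integer seed for simulated inputs.
#' @return invisibly, a list with `events`, `summaries` and `stats`
#'   tibbles (also written to `out_dir`).
#' @export
run_fly_pipeline <- function(cfg, seed = 1) {
  cfg <- read_config(cfg)
  require_keys(cfg, "out_dir", "fly pipeline")
  if (is.null(cfg$tracks) && is.null(cfg$sim)) {
    stop_socioscope("fly pipeline config missing key(s): tracks or sim")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  arena <- do.call(arena_config, cfg$arena %||% list())
  params <- do.call(detector_params, cfg$detector %||% list())

  tracksets <- list()
  if (!is.null(cfg$tracks)) {
    for (tr in cfg$tracks) {
      require_keys(tr, c("path", "sex", "genotype"), "tracks entry")
      ts <- read_trackset(tr$path, arena,
                          group_meta = list(sex = tr$sex,
                                            genotype = tr$genotype,
                                            arena_id = tr$arena_id %||% tr$path),
                          body_length_mm = tr$body_length_mm %||% 2.5)
      tracksets[[length(tracksets) + 1]] <- ts
    }
  }
  if (!is.null(cfg$sim)) {
    idx <- 0
    for (blk in cfg$sim) {
      require_keys(blk, c("sex", "genotype"), "sim entry")
      n_arenas <- blk$n_arenas %||% 1
      sp_args <- blk[setdiff(names(blk), c("sex", "genotype", "n_arenas"))]
      for (r in seq_len(n_arenas)) {
        idx <- idx + 1
        sp <- do.call(sim_fly_params,
                      c(sp_args, list(arena = arena,
                                      seed = substream_seed(seed, idx))))
        ts <- simulate_fly_arena(sp)
        attr(ts, "group_meta") <- list(sex = blk$sex, genotype = blk$genotype,
                                       arena_id = sprintf("sim_%03d", idx))
        tracksets[[length(tracksets) + 1]] <- ts
      }
    }
  }

  message(sprintf("[fly] detecting interactions in %d arena recording(s)",
                  length(tracksets)))
  events <- purrr::map(tracksets, function(ts) {
    ev <- detect_interactions(ts, params)
    meta <- group_meta(ts)
    dplyr::mutate(ev, arena_id = meta$arena_id %||% NA_character_)
  }) |> dplyr::bind_rows()
  summaries <- purrr::map(tracksets, summarize_group) |> dplyr::bind_rows()

  message("[fly] fitting group models")
  responses <- cfg$responses %||%
    c("n_interactions", "mean_duration_s", "mean_speed_mm_s")
  fam_for <- c(n_interactions = "poisson", mean_duration_s = "gamma",
               mean_speed_mm_s = "gaussian")
  stats_tb <- purrr::map(responses, function(r) {
    fit <- try(fit_group_model(summaries, r, family = fam_for[[r]]),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    dplyr::bind_cols(tidy(fit),
                     glance(fit)[c("shapiro_W", "shapiro_p",
                                   "joint_statistic", "joint_df", "joint_p")])
  }) |> dplyr::bind_rows()

  utils::write.csv(events, file.path(cfg$out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(cfg$out_dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_tb, file.path(cfg$out_dir, "stats.csv"),
                   row.names = FALSE)
  write_provenance(cfg, seed, cfg$out_dir)
  invisible(list(events = events, summaries = summaries, stats = stats_tb))
}

#' Run the mouse longitudinal analysis end to end
#'
#' Composes event-log binning, log transform, nest covariate and the
#' penalized-spline contrast; with an injection schedule it instead runs
#' the hour-matched baseline-delta analysis and contrasts drug against
#' vehicle deltas. Outputs per-behavior curve CSVs, a JSON report of the
#' interaction and overall tests, and a provenance JSON.
#'
#' @param cfg list or YAML path. Required: `out_dir`, `events` (path to
#'   an event-log CSV, or a tibble), `behaviors` (non-empty character
#'   vector). For the genetic design: `groups`, a named list mapping
#'   group label to subject ids. For the injection design: `schedule`
#'   (CSV path or tibble with `subject_id`, `injection_hour`,
#'   `treatment`). Optional: `hours`, `k`, `family`, `log_offset`,
#'   `dark_onset_hour`.
#' @param seed integer seed (recorded in provenance; the analysis itself
#'   is deterministic).
#' @return invisibly, a list of per-behavior results (`contrast_fit`s
#'   and curve tibbles).
#' @export
run_mouse_pipeline <- function(cfg, seed = 1) {
  cfg <- read_config(cfg)
  require_keys(cfg, c("out_dir", "events", "behaviors"), "mouse pipeline")
  if (length(cfg$behaviors) == 0) {
    stop_socioscope("empty behavior vocabulary in mouse pipeline config")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  events <- if (is.character(cfg$events)) {
    tibble::as_tibble(utils::read.csv(cfg$events, stringsAsFactors = FALSE))
  } else tibble::as_tibble(cfg$events)
  events <- validate_events(events)
  dark_onset <- cfg$dark_onset_hour %||% 0
  hours <- cfg$hours %||% (ceiling(max(events$stop_s) / 3600 / 24) * 24)
  offset <- cfg$log_offset %||% 1

  results <- list()
  for (b in cfg$behaviors) {
    message(sprintf("[mouse] %s: binning and modeling", b))
    family <- if (b == "distance_step") "quasipoisson" else "gaussian"
    ts <- bin_durations(events, b, hours, dark_onset_hour = dark_onset)
    nest <- nest_covariate(events, hours, dark_onset_hour = dark_onset)
    ts <- dplyr::left_join(ts, nest, by = c("subject_id", "hour")) |>
      dplyr::mutate(nest_s = dplyr::coalesce(.data$nest_s, 0))

    if (!is.null(cfg$schedule)) {
      schedule <- if (is.character(cfg$schedule)) {
        tibble::as_tibble(utils::read.csv(cfg$schedule,
                                          stringsAsFactors = FALSE))
      } else tibble::as_tibble(cfg$schedule)
      deltas <- baseline_delta(ts, schedule) |>
        dplyr::rename(hour = "hour_post", value = "delta", group = "treatment")
      fit <- analyze_contrast(deltas, k = min(cfg$k %||% 10, 10),
                              family = "gaussian")
    } else {
      require_keys(cfg, "groups", "mouse pipeline (genetic design)")
      grp_map <- purrr::imap(cfg$groups, function(subs, g) {
        tibble::tibble(subject_id = subs, group = g)
      }) |> dplyr::bind_rows()
      dat <- dplyr::inner_join(ts, grp_map, by = "subject_id")
      if (family == "gaussian") dat <- log_transform(dat, offset)
      fit <- analyze_contrast(dat, k = cfg$k %||% 30, family = family)
    }
    curve <- tidy(fit)
    utils::write.csv(curve, file.path(cfg$out_dir,
                                      sprintf("curve_%s.csv", b)),
                     row.names = FALSE)
    jsonlite::write_json(
      as.list(glance(fit)),
      file.path(cfg$out_dir, sprintf("report_%s.json", b)),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results[[b]] <- fit
  }
  write_provenance(cfg, seed, cfg$out_dir)
  invisible(results)
}
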