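#' Build a trackset from a per-frame trajectory table
#'
#' A trackset is the package's container for one arena recording: a tibble
#' with one row per individual per frame and columns `individual_id`,
#' `frame`, `x_mm`, `y_mm`, `heading_rad`, `valid`, `body_length_mm`, plus
#' the arena description and group metadata carried as attributes. All
#' frames are aligned to a common 0-based index across individuals; frames
#' an individual was not tracked on are present with `valid = FALSE` and
#' are never silently interpolated.
#'
#' @param df data frame with columns `id`, `frame`, `x`, `y`, `heading`
#'   and optionally `body_length`. Positions are divided by
#'   `arena$px_per_mm`; headings are radians and are wrapped into
#'   `[-pi, pi)`.
#' @param arena an [arena_config()].
#' @param group_meta named list of recording-level labels (genotype, sex,
#'   arena/replicate id, ...).
#' @param body_length_mm fallback body length in mm used for individuals
#'   whose table carries no per-frame `body_length` column.
#' @param bounds_tol_mm tolerance, in mm, allowed beyond the arena walls
#'   before a valid position is rejected (wall-contact slack).
#' @return a `trackset` tibble.
#' @export
as_trackset <- function(df, arena, group_meta = list(),
                        body_length_mm = NULL, bounds_tol_mm = 2) {
  stopifnot(inherits(arena, "arena_config"))
  need <- c("id", "frame", "x", "y", "heading")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_socioscope("trajectory table lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  if (!is.numeric(df$frame) || anyNA(df$frame) || any(df$frame %% 1 != 0)) {
    stop_socioscope("`frame` must be integer-valued and non-missing")
  }
  if (anyDuplicated(df[c("id", "frame")]) > 0) {
    stop_socioscope("duplicated (id, frame) pairs in trajectory table")
  }
  mono <- df |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(ok = all(diff(.data$frame) > 0), .groups = "drop")
  if (!all(mono$ok)) {
    stop_socioscope("frames are not strictly increasing for id(s): %s",
                    paste(mono$id[!mono$ok], collapse = ", "))
  }

  # per-individual body length: median of per-frame posture lengths when
  # exported, else the configured constant
  bl <- df |>
    dplyr::group_by(id = .data$id) |>
    dplyr::summarise(
      body_length_mm = estimate_body_length(
        if ("body_length" %in% names(df)) {
          .data$body_length / arena$px_per_mm
        } else NULL,
        default = body_length_mm
      ),
      .groups = "drop"
    )

  frame0 <- min(df$frame)
  obs <- df |>
    dplyr::transmute(
      individual_id = as.character(.data$id),
      frame = as.integer(.data$frame - frame0),
      x_mm = .data$x / arena$px_per_mm,
      y_mm = .data$y / arena$px_per_mm,
      heading_rad = wrap_angle(.data$heading),
      valid = TRUE
    )

  out_x <- obs$x_mm < -bounds_tol_mm | obs$x_mm > arena$width_mm + bounds_tol_mm
  out_y <- obs$y_mm < -bounds_tol_mm | obs$y_mm > arena$height_mm + bounds_tol_mm
  if (any(out_x | out_y)) {
    stop_socioscope(
      "%d valid position(s) fall outside the %g x %g mm arena (tol %g mm)",
      sum(out_x | out_y), arena$width_mm, arena$height_mm, bounds_tol_mm
    )
  }

  domain <- tidyr::expand_grid(
    individual_id = sort(unique(obs$individual_id)),
    frame = 0:max(obs$frame)
  )
  tracks <- domain |>
    dplyr::left_join(obs, by = c("individual_id", "frame")) |>
    dplyr::mutate(valid = !is.na(.data$valid)) |>
    dplyr::left_join(
      dplyr::mutate(bl, id = as.character(.data$id)) |>
        dplyr::select(individual_id = "id", "body_length_mm"),
      by = "individual_id"
    ) |>
    dplyr::arrange(.data$individual_id, .data$frame)

  new_trackset(tracks, arena, group_meta)
}

new_trackset <- function(tracks, arena, group_meta = list()) {
  structure(
    tracks,
    arena = arena,
    group_meta = group_meta,
    class = c("trackset", class(tibble::as_tibble(tracks)))
  )
}

#' @export
print.trackset <- function(x, ...) {
  a <- arena(x)
  ids <- unique(x$individual_id)
  cat(sprintf(
    "<trackset> %d individuals x %d frames (%.1f s @ %g Hz), arena %g x %g mm\n",
    length(ids), max(x$frame) + 1L, (max(x$frame) + 1L) / a$frame_rate_hz,
    a$frame_rate_hz, a$width_mm, a$height_mm
  ))
  NextMethod()
}

#' Accessors for trackset attributes
#'
#' @param ts a `trackset`.
#' @return [arena()] the `arena_config`; [group_meta()] the metadata list.
#' @export
arena <- function(ts) {
  a <- attr(ts, "arena", exact = TRUE)
  if (is.null(a)) stop_socioscope("object carries no arena_config")
  a
}

#' @rdname arena
#' @export
group_meta <- function(ts) attr(ts, "group_meta", exact = TRUE) %||% list()

#' Read a tracker export into a trackset
#'
#' Accepts the long-format delimited dialect written by common
#' multi-animal trackers: one row per individual per frame with columns
#' `id`, `frame`, `x`, `y`, `heading` and optionally `body_length`.
#' Comma- and tab-delimited files are both accepted (`.tsv`/`.tab` imply
#' tabs). Unit handling, frame alignment and validation are those of
#' [as_trackset()]. The column contract is documented in
#' `system.file("extdata", "track_table_schema.yaml", package = "socioscope")`.
#'
#' @inheritParams as_trackset
#' @param path path to the delimited table.
#' @return a `trackset` tibble.
#' @seealso [write_trackset()] for the inverse; the pair round-trips all
#'   fields exactly.
#' @export
read_trackset <- function(path, arena, group_meta = list(),
                          body_length_mm = NULL, bounds_tol_mm = 2) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  as_trackset(df, arena, group_meta = group_meta,
              body_length_mm = body_length_mm, bounds_tol_mm = bounds_tol_mm)
}

#' Write a trackset back to the long-format delimited dialect
#'
#' Only valid frames are written (gaps are re-derived on reading);
#' positions are written in mm at full double precision so that
#' read-write-read is idempotent on every field.
#'
#' @param ts a `trackset`.
#' @param path output file path (`.tsv`/`.tab` for tabs, else commas).
#' @return `path`, invisibly.
#' @export
write_trackset <- function(ts, path) {
  stopifnot(inherits(ts, "trackset"))
  out <- ts |>
    dplyr::filter(.data$valid) |>
    dplyr::transmute(
      id = .data$individual_id, frame = .data$frame,
      x = .data$x_mm, y = .data$y_mm, heading = .data$heading_rad,
      body_length = .data$body_length_mm
    )
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 17, format = "g"))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Consolidate per-frame body lengths into one per-individual value
#'
#' Trackers report a posture-derived body length every frame; a single
#' robust value per individual is needed to express the proximity
#' threshold in body-length units. The median over frames is used so that
#' occasional segmentation blow-ups do not bias the scale.
#'
#' @param per_frame_lengths numeric vector of per-frame body lengths in mm
#'   (non-finite entries dropped), or `NULL` when the export has none.
#' @param default fallback constant in mm used when no per-frame lengths
#'   are available.
#' @return a single positive body length in mm.
#' @export
#' @examples
#' estimate_body_length(c(2.4, 2.5, 2.6, 50))   # robust to the outlier
#' estimate_body_length(NULL, default = 2.5)
estimate_body_length <- function(per_frame_lengths = NULL, default = NULL) {
  if (!is.null(per_frame_lengths)) {
    per_frame_lengths <- per_frame_lengths[is.finite(per_frame_lengths)]
  }
  if (length(per_frame_lengths) > 0) {
    bl <- stats::median(per_frame_lengths)
  } else if (!is.null(default)) {
    bl <- default
  } else {
    stop_socioscope(
      "no body length available: supply per-frame lengths or a default")
  }
  if (!is.finite(bl) || bl <= 0) {
    stop_socioscope("body length must be positive, got %g", bl)
  }
  bl
}
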