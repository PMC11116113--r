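#' Arena configuration
#'
#' Describes the recording arena and the units of a tracker export. The
#' default geometry is a 66 x 40 mm rectangular walking arena for groups of
#' four flies; coordinates are 0-based with the origin at the lower-left
#' corner and y pointing up.
#'
#' @param width_mm,height_mm arena extent in mm; must be positive.
#' @param frame_rate_hz acquisition frame rate in Hz. Trackers rarely embed
#'   it in their exports, so it is declared here; must be positive.
#' @param px_per_mm scale of the export's coordinates. `1` means the input
#'   is already metric; raw pixel exports give the camera calibration here.
#' @return an object of class `arena_config` (a named list).
#' @export
#' @examples
#' arena_config()                     # the default 66 x 40 mm arena
#' arena_config(px_per_mm = 10)       # a raw pixel export at 10 px/mm
arena_config <- function(width_mm = 66, height_mm = 40,
                         frame_rate_hz = 30, px_per_mm = 1) {
  for (nm in c("width_mm", "height_mm", "frame_rate_hz", "px_per_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_socioscope("`%s` must be a single positive number", nm)
    }
  }
  structure(
    list(width_mm = width_mm, height_mm = height_mm,
         frame_rate_hz = frame_rate_hz, px_per_mm = px_per_mm),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %.6g x %.6g mm @ %.6g Hz (%.6g px/mm)\n",
              x$width_mm, x$height_mm, x$frame_rate_hz, x$px_per_mm))
  invisible(x)
}

#' Read or write an arena configuration as YAML
#'
#' @param path file path of a YAML mapping with keys `width_mm`,
#'   `height_mm`, `frame_rate_hz`, `px_per_mm` (missing keys fall back to
#'   the [arena_config()] defaults).
#' @return [read_arena_config()] returns an `arena_config`;
#'   [write_arena_config()] returns `path` invisibly.
#' @export
read_arena_config <- function(path) {
  y <- yaml::read_yaml(path)
  arena_config(
    width_mm = y$width_mm %||% 66,
    height_mm = y$height_mm %||% 40,
    frame_rate_hz = y$frame_rate_hz %||% 30,
    px_per_mm = y$px_per_mm %||% 1
  )
}

#' @rdname read_arena_config
#' @param arena an `arena_config`.
#' @export
write_arena_config <- function(arena, path) {
  stopifnot(inherits(arena, "arena_config"))
  yaml::write_yaml(unclass(arena), path)
  invisible(path)
}
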