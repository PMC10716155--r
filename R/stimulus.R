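#' Generate a binary checkerboard noise clip
#'
#' Draws a spatiotemporal binary white-noise stimulus: every checker on every
#' frame is set independently and equiprobably to -1 or +1 (zero-mean contrast
#' coding).  Typical parameterizations follow the two regimes used for mouse
#' retina: 150-um squares refreshed every 66 ms at scotopic/mesopic light
#' levels, and 75-um squares refreshed every 33 ms at photopic levels.
#'
#' @param n_frames number of stimulus frames (>= 1).
#' @param n_rows,n_cols checkerboard grid size (>= 1 each).
#' @param square_size_um side length of one checker square, in micrometers.
#' @param refresh_ms frame duration in milliseconds (> 0).
#' @param seed integer seed; the same seed and geometry reproduce the clip
#'   bit-exactly.
#' @param light_level_rh nominal light level tag in Rh*/rod/s (metadata only;
#'   the stimulus itself is always unit-contrast binary noise).
#'
#' @return A \code{stimulus_clip}: a list with \code{frames} (3-D array
#'   indexed frame x row x col with values in \{-1, +1\}), the geometry and
#'   timing metadata above, \code{seed}, and \code{n_repeats = 1}.
#' @examples
#' clip <- generate_checkerboard(100, 8, 8, square_size_um = 75,
#'                               refresh_ms = 33, seed = 1)
#' clip_duration_s(clip)
#' @export
generate_checkerboard <- function(n_frames, n_rows, n_cols,
                                  square_size_um = 75, refresh_ms = 33,
                                  seed = 1, light_level_rh = 10000) {
  if (n_frames < 1 || n_rows < 1 || n_cols < 1)
    stop("all stimulus dimensions must be >= 1")
  if (refresh_ms <= 0) stop("refresh_ms must be > 0")
  frames <- with_seed(seed, array(
    sample(c(-1, 1), n_frames * n_rows * n_cols, replace = TRUE),
    dim = c(n_frames, n_rows, n_cols)))
  new_stimulus_clip(frames, square_size_um, refresh_ms, seed,
                    light_level_rh = light_level_rh, n_repeats = 1L)
}

new_stimulus_clip <- function(frames, square_size_um, refresh_ms, seed,
                              light_level_rh = NA_real_, n_repeats = 1L) {
  structure(list(frames = frames,
                 square_size_um = square_size_um,
                 refresh_ms = refresh_ms,
                 light_level_rh = light_level_rh,
                 seed = seed,
                 n_repeats = as.integer(n_repeats)),
            class = "stimulus_clip")
}

#' @export
print.stimulus_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Binary checkerboard clip: %d frames of %d x %d checkers (%g um, %g ms)\n",
    d[1], d[2], d[3], x$square_size_um, x$refresh_ms))
  cat(sprintf("  duration %.3f s%s, light level %g Rh*/rod/s, seed %d\n",
              clip_duration_s(x),
              if (x$n_repeats > 1L)
                sprintf(" per repeat x %d repeats", x$n_repeats) else "",
              x$light_level_rh, x$seed))
  invisible(x)
}

#' Duration of one presentation of a clip, in seconds
#' @param clip a \code{stimulus_clip}.
#' @export
clip_duration_s <- function(clip) {
  dim(clip$frames)[1] * clip$refresh_ms / 1000
}

#' Cut a clip for repeated presentation
#'
#' Takes the first \code{clip_duration_s} seconds of an existing clip and
#' marks it for \code{n_repeats} consecutive presentations, mirroring the
#' repeat protocol of 10-s clips presented 100 times.  Frames per repeat is
#' \code{floor(clip_duration_s * 1000 / refresh_ms)}; a partial trailing
#' frame is dropped.
#'
#' @param clip a \code{stimulus_clip}.
#' @param clip_duration_s duration to keep, seconds.
#' @param n_repeats number of presentations (>= 1).
#' @return A \code{stimulus_clip} with the truncated frames and
#'   \code{n_repeats} set; total presented duration is
#'   \code{clip_duration_s(out) * n_repeats}.
#' @export
make_repeat_clip <- function(clip, clip_duration_s = 10, n_repeats = 100) {
  stopifnot(inherits(clip, "stimulus_clip"))
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  n_keep <- floor(clip_duration_s * 1000 / clip$refresh_ms)
  if (n_keep < 1) stop("clip_duration_s shorter than one frame")
  if (n_keep > dim(clip$frames)[1])
    stop(sprintf("clip too short: need %d frames, have %d",
                 n_keep, dim(clip$frames)[1]))
  out <- clip
  out$frames <- clip$frames[seq_len(n_keep), , , drop = FALSE]
  out$n_repeats <- as.integer(n_repeats)
  out
}

#' Unfold a clip's frames into a frames x checkers matrix
#'
#' Row-major checker order: checker (row r, col c) maps to column
#' (r - 1) * n_cols + c.  Used by the reverse-correlation and simulation
#' code; exported because downstream linear algebra is easiest on this form.
#' @param clip a \code{stimulus_clip}.
#' @export
clip_matrix <- function(clip) {
  d <- dim(clip$frames)
  m <- matrix(0, d[1], d[2] * d[3])
  for (r in seq_len(d[2]))
    m[, (r - 1) * d[3] + seq_len(d[3])] <- clip$frames[, r, ]
  m
}

#' Checker center coordinates in micrometers
#'
#' Origin at the top-left corner of checker (1, 1); checker centers at
#' (col - 0.5, row - 0.5) * square size.  Order matches
#' \code{\link{clip_matrix}} columns.
#' @param clip a \code{stimulus_clip}.
#' @return data.frame with \code{x_um}, \code{y_um}, \code{row}, \code{col}.
#' @export
checker_centers_um <- function(clip) {
  d <- dim(clip$frames)
  grid <- expand.grid(col = seq_len(d[3]), row = seq_len(d[2]))
  grid <- grid[order(grid$row, grid$col), ]
  data.frame(x_um = (grid$col - 0.5) * clip$square_size_um,
             y_um = (grid$row - 0.5) * clip$square_size_um,
             row = grid$row, col = grid$col)
}

#' Save / load a stimulus clip
#'
#' The frame array is stored as a compressed binary file and the metadata
#' (geometry, refresh, seed, light level, repeats) as a JSON sidecar next to
#' it, so a clip can be regenerated or audited without loading the array.
#' @param clip a \code{stimulus_clip}.
#' @param path file path for the binary array (the sidecar adds ".json").
#' @export
write_clip <- function(clip, path) {
  meta <- clip[setdiff(names(clip), "frames")]
  meta$dim <- dim(clip$frames)
  saveRDS(clip$frames, path, compress = "gzip")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_clip
#' @export
read_clip <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- readRDS(path)
  new_stimulus_clip(frames, meta$square_size_um, meta$refresh_ms, meta$seed,
                    light_level_rh = meta$light_level_rh,
                    n_repeats = meta$n_repeats)
}
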