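#' Movie stack container
#'
#' Time-ordered stack of raw grayscale intensity frames, the unit handled by
#' the background and detection stages and produced by the simulator.
#' Frames are stored as an `H x W x T` array (row = y, column = x); pixel
#' `(r, c)` (0-based) has its centre at `((c + 0.5), (r + 0.5)) * pixel_nm`.
#'
#' @param frames `H x W x T` numeric array of non-negative intensities, or a
#'   single `H x W` matrix for a one-frame movie.
#' @param pixel_nm Pixel pitch in nm.
#' @param frame_rate_hz Acquisition rate in Hz.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_nm, frame_rate_hz) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_invalid("frames must be an H x W x T array")
  if (dim(frames)[3] < 1L) stop_invalid("movie needs at least one frame")
  if (anyNA(frames) || any(frames < 0))
    stop_invalid("intensities must be finite and non-negative")
  check_scalar_pos(pixel_nm, "pixel_nm")
  check_scalar_pos(frame_rate_hz, "frame_rate_hz")
  structure(list(frames = frames, pixel_nm = pixel_nm,
                 frame_rate_hz = frame_rate_hz),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d frames of %d x %d px (%.0f nm/px, %.1f Hz)\n",
              d[3], d[1], d[2], x$pixel_nm, x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$frames)

# Internal constructor for ratiometric contrast stacks. `valid_frame_offset`
# is the 0-based index of the first raw frame that has a defined background;
# `raw_frame_index` maps each contrast frame back to its raw frame (1-based).
contrast_stack <- function(frames, pixel_nm, frame_rate_hz,
                           valid_frame_offset, raw_frame_index) {
  structure(list(frames = frames, pixel_nm = pixel_nm,
                 frame_rate_hz = frame_rate_hz,
                 valid_frame_offset = valid_frame_offset,
                 raw_frame_index = raw_frame_index),
            class = "contrast_stack")
}

#' @export
print.contrast_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "contrast_stack: %d frames of %d x %d px (first valid raw frame %d)\n",
    d[3], d[1], d[2], x$valid_frame_offset))
  invisible(x)
}

#' @export
dim.contrast_stack <- function(x) dim(x$frames)
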