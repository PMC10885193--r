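#' Running scattering background
#'
#' Per-pixel running mean or running temporal median over the `window`
#' frames strictly preceding each frame. The static hBN scattering pattern
#' varies slowly compared with molecular binding, so a short trailing
#' window tracks it while a transient molecule (often present for a single
#' frame) leaves the median untouched. The current frame is excluded so
#' that a short-lived particle is never partially subtracted from itself.
#' The first `window` frames have no defined background and are dropped.
#'
#' @param stack A [movie_stack()].
#' @param window Number of preceding frames (1 <= window < T; default 75,
#'   about 0.83 s at 90.5 Hz). A molecule present for a substantial part
#'   of the window drags the median toward particle values — fully once
#'   present for half the window, and partially (by pushing the median
#'   into the tail of the noise distribution) well before that — leaving
#'   an inverted ghost for up to `window` frames after departure. The
#'   window should be at least about three times the longest common
#'   dwell.
#' @param mode `"median"` (default) or `"mean"`.
#' @return A list of class `background_stack`: `frames` (H x W x (T -
#'   window) array), `valid_frame_offset` (0-based index of the first raw
#'   frame with a background), `raw_frame_index` (1-based raw indices),
#'   `window`, `mode`.
#' @export
running_background <- function(stack, window = 75,
                               mode = c("median", "mean")) {
  mode <- match.arg(mode)
  d <- dim(stack$frames)
  if (window < 1 || window >= d[3])
    stop_invalid("window must satisfy 1 <= window < n_frames (got ",
                 window, " for ", d[3], " frames)")
  t_by_px <- matrix(aperm(stack$frames, c(3, 1, 2)),
                    nrow = d[3], ncol = d[1] * d[2])
  bg <- cpp_running_background(t_by_px, as.integer(window),
                               mode == "median")
  bg <- aperm(array(bg, c(d[3] - window, d[1], d[2])), c(2, 3, 1))
  structure(list(frames = bg,
                 valid_frame_offset = as.integer(window),
                 raw_frame_index = (window + 1L):d[3],
                 window = as.integer(window), mode = mode),
            class = "background_stack")
}

#' Ratiometric contrast
#'
#' Converts raw intensities to the dimensionless ratiometric contrast
#' `(I - B) / B` against a per-frame background estimate. On clean
#' background the contrast fluctuates around zero; a bound molecule appears
#' as a signed deviation whose sign encodes constructive versus destructive
#' interference. Pixels with background 0 are flagged invalid (`NA`) and
#' excluded from detection.
#'
#' @param stack A [movie_stack()].
#' @param background A `background_stack` from [running_background()]
#'   computed on the same movie.
#' @return A `contrast_stack` whose frames align with
#'   `background$raw_frame_index`.
#' @export
ratiometric_contrast <- function(stack, background) {
  d <- dim(stack$frames)
  db <- dim(background$frames)
  if (!all(d[1:2] == db[1:2]) ||
      db[3] != length(background$raw_frame_index))
    stop_invalid("movie and background shapes do not align")
  if (all(background$frames == 0))
    stop_invalid("background is zero everywhere; contrast is undefined")
  idx <- background$raw_frame_index
  I <- stack$frames[, , idx, drop = FALSE]
  B <- background$frames
  contrast <- (I - B) / B
  contrast[B == 0] <- NA_real_
  contrast_stack(contrast, stack$pixel_nm, stack$frame_rate_hz,
                 valid_frame_offset = background$valid_frame_offset,
                 raw_frame_index = idx)
}

#' Background removal in one step
#'
#' @inheritParams running_background
#' @return A `contrast_stack`.
#' @export
compute_contrast <- function(stack, window = 75,
                             mode = c("median", "mean")) {
  ratiometric_contrast(stack, running_background(stack, window, mode))
}
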