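#' Detection configuration
#'
#' @param threshold Minimum absolute ratiometric contrast for a pixel to be
#'   considered part of a blob. Usually calibrated per movie with
#'   [estimate_threshold()].
#' @param min_area_px Minimum connected-region size in pixels (default 4,
#'   suppressing single-pixel noise excursions).
#' @param connectivity 4 or 8 (default 8, so that the bright and dark lobes
#'   of an interferometric blob stay one detection when diagonally
#'   contiguous).
#' @param edge_margin_px Regions with any pixel within this border band are
#'   discarded (default 1).
#' @param smooth_sigma_px Gaussian matched-filter width applied to the
#'   absolute-contrast image before thresholding (default 2 px; 0 disables
#'   smoothing). A bound coil images as several interference lobes of
#'   either sign; smoothing `|c|` bridges the sub-threshold gaps between
#'   the lobes of one molecule and suppresses single-pixel noise, so a
#'   molecule segments as one region.
#' @param peak_min_sep_px Minimum separation of intensity peaks within a
#'   connected region (default 14 px, about the diameter over which two
#'   20 kbp coils physically overlap). A region holding several peaks at
#'   least this far apart is split between them (each pixel assigned to
#'   its nearest peak), so that molecules whose supra-threshold footprints
#'   touch are still localized individually. 0 disables splitting.
#' @param centroid_sigma_px Smoothing width for the centroid weights
#'   (default 12 px, about one coil radius). The interference lobes of one
#'   molecule land at random positions within its footprint, so weighting
#'   the centre of mass by the coil-scale envelope of `|c|` rather than by
#'   the sharper matched-filter image averages over the lobes and roughly
#'   halves the localization scatter. 0 reuses the matched-filter image.
#' @export
detection_config <- function(threshold, min_area_px = 4, connectivity = 8,
                             edge_margin_px = 1, smooth_sigma_px = 2,
                             peak_min_sep_px = 14, centroid_sigma_px = 12) {
  check_scalar_pos(threshold, "threshold")
  if (min_area_px < 1) stop_invalid("min_area_px must be >= 1")
  if (!connectivity %in% c(4, 8)) stop_invalid("connectivity must be 4 or 8")
  if (edge_margin_px < 0) stop_invalid("edge_margin_px must be >= 0")
  if (smooth_sigma_px < 0) stop_invalid("smooth_sigma_px must be >= 0")
  if (peak_min_sep_px < 0) stop_invalid("peak_min_sep_px must be >= 0")
  if (centroid_sigma_px < 0) stop_invalid("centroid_sigma_px must be >= 0")
  structure(list(threshold = threshold,
                 min_area_px = as.integer(min_area_px),
                 connectivity = as.integer(connectivity),
                 edge_margin_px = as.integer(edge_margin_px),
                 smooth_sigma_px = smooth_sigma_px,
                 peak_min_sep_px = as.integer(peak_min_sep_px),
                 centroid_sigma_px = centroid_sigma_px),
            class = "detection_config")
}

#' Separable Gaussian smoothing of an image
#'
#' Convolution with a normalised Gaussian kernel (radius 3 sigma), edges
#' renormalised so flat regions stay flat.
#'
#' @param img Numeric matrix (`NA` treated as 0).
#' @param sigma_px Kernel width in pixels; 0 returns the input unchanged.
#' @return Smoothed matrix.
#' @export
smooth_image <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  img[is.na(img)] <- 0
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  band <- function(n) {
    M <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      ok <- i + d >= 1 & i + d <= n
      M[cbind(i[ok], (i + d)[ok])] <- k[d + r + 1]
    }
    M / rowSums(M)
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

#' Absolute contrast image
#'
#' Pixelwise `|c|`. Constructive and destructive interference give a bound
#' molecule lobes of either sign; taking the absolute value lets one
#' threshold capture both.
#'
#' @param frame A signed contrast image (matrix).
#' @return The non-negative absolute-contrast image.
#' @export
absolute_contrast <- function(frame) abs(frame)

#' Robust detection threshold from the contrast noise floor
#'
#' The threshold applies to the smoothed absolute-contrast image that
#' [detect_frame()] segments. On particle-free background that image
#' fluctuates around a positive noise baseline, so each sampled frame
#' contributes a robust estimate `median + k * MAD * 1.4826` (median =
#' baseline, scaled median absolute deviation = spread); the threshold is
#' the median of the per-frame estimates. Particles are sparse, so the
#' frame median is dominated by background. `k = 8` trades false positives
#' from the noisy background against sensitivity to faint blobs; blobs at
#' the default simulated signal-to-noise sit an order of magnitude above
#' the baseline, so the margin costs little sensitivity.
#'
#' @param cstack A `contrast_stack`, or a single contrast matrix.
#' @param k Multiplier of the robust noise sigma (default 8).
#' @param max_frames Number of frames to sample for the estimate
#'   (default 50).
#' @param smooth_sigma_px Matched-filter width; must equal the
#'   `smooth_sigma_px` of the [detection_config()] the threshold will be
#'   used with, so that threshold and image are on the same scale
#'   (default 2).
#' @return Threshold in absolute-contrast units of the (smoothed) image.
#' @export
estimate_threshold <- function(cstack, k = 8, max_frames = 50,
                               smooth_sigma_px = 2) {
  frames <- if (inherits(cstack, "contrast_stack")) cstack$frames
            else array(cstack, c(dim(cstack), 1L))
  nt <- dim(frames)[3]
  use <- unique(round(seq(1, nt, length.out = min(nt, max_frames))))
  thr <- vapply(use, function(t) {
    s <- smooth_image(abs(frames[, , t]), smooth_sigma_px)
    median(s, na.rm = TRUE) + k * mad(s, na.rm = TRUE)
  }, 0)
  median(thr)
}

#' Segment supra-threshold regions
#'
#' Connected components (4- or 8-connectivity) of the pixels whose absolute
#' contrast reaches the threshold, discarding regions smaller than
#' `min_area_px` and regions touching the `edge_margin_px` border band.
#'
#' @param frame_abs Non-negative absolute-contrast image (`NA` treated as
#'   below threshold).
#' @param cfg A [detection_config()].
#' @return A list with `labels` (H x W integer matrix, 0 = background) and
#'   `ids` (labels that survived the filters).
#' @export
segment <- function(frame_abs, cfg) {
  mask <- frame_abs >= cfg$threshold
  mask[is.na(mask)] <- FALSE
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(frame_abs)),
                              cfg$connectivity)
  ids <- integer(0)
  if (any(mask)) {
    areas <- tabulate(lab[lab > 0])
    ids <- which(areas >= cfg$min_area_px)
    m <- cfg$edge_margin_px
    if (m > 0 && length(ids)) {
      H <- nrow(lab); W <- ncol(lab)
      border <- unique(c(lab[seq_len(m), ], lab[(H - m + 1):H, ],
                         lab[, seq_len(m)], lab[, (W - m + 1):W]))
      ids <- setdiff(ids, border)
    }
  }
  lab[!(lab %in% ids)] <- 0L
  list(labels = lab, ids = sort(ids))
}

#' Contrast-weighted centroid of one region
#'
#' The blob position is the centre of mass of its member pixels weighted by
#' absolute contrast: `x = sum(x_p |c_p|) / sum(|c_p|)` (same for y).
#' Pixel coordinates follow the pixel-centre convention: 0-based pixel `i`
#' spans `[i, i+1)` with centre `i + 0.5`, so positions in nm are
#' `coordinate_px * pixel_nm`.
#'
#' @param frame_abs Absolute-contrast image.
#' @param labels Label matrix from [segment()].
#' @param id Region label to localize.
#' @param pixel_nm Pixel pitch.
#' @param frame Frame index recorded in the output.
#' @return One-row data frame: `frame`, `x_px`, `y_px`, `x_nm`, `y_nm`,
#'   `area_px`, `mean_abs_contrast`, `label`.
#' @export
weighted_centroid <- function(frame_abs, labels, id, pixel_nm, frame = NA_integer_) {
  sel <- which(labels == id, arr.ind = TRUE)
  if (nrow(sel) == 0) stop_invalid("region ", id, " is empty")
  w <- frame_abs[sel]
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0)
    stop_invalid("region ", id, " has zero total absolute contrast")
  # rows/cols are 1-based; (i - 1) + 0.5 = i - 0.5 is the pixel centre
  x_px <- sum((sel[, "col"] - 0.5) * w) / sw
  y_px <- sum((sel[, "row"] - 0.5) * w) / sw
  data.frame(frame = frame, x_px = x_px, y_px = y_px,
             x_nm = x_px * pixel_nm, y_nm = y_px * pixel_nm,
             area_px = nrow(sel), mean_abs_contrast = mean(w), label = id)
}

#' Detect blobs in one contrast frame
#'
#' @param cframe Signed contrast image.
#' @param cfg A [detection_config()].
#' @param pixel_nm Pixel pitch.
#' @param frame Frame index recorded in the output.
#' @return Localization data frame (possibly empty).
#' @export
detect_frame <- function(cframe, cfg, pixel_nm, frame = NA_integer_) {
  # smoothing is a convex average, so it cannot raise the maximum: a frame
  # whose raw |c| peak is below threshold has no supra-threshold region
  if (max(abs(cframe), na.rm = TRUE) < cfg$threshold)
    return(empty_localizations())
  fa <- smooth_image(absolute_contrast(cframe), cfg$smooth_sigma_px)
  # segment without the border filter; the filter is applied to the split
  # fragments below, so one molecule near the border does not veto a large
  # merged region
  cfg0 <- cfg; cfg0$edge_margin_px <- 0L
  seg <- segment(fa, cfg0)
  if (length(seg$ids) == 0) return(empty_localizations())
  labels <- split_regions_at_peaks(fa, seg, cfg)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) return(empty_localizations())
  fw <- if (cfg$centroid_sigma_px > 0)
    smooth_image(absolute_contrast(cframe), cfg$centroid_sigma_px) else fa
  out <- do.call(rbind, lapply(ids, function(id)
    weighted_centroid(fw, labels, id, pixel_nm, frame)))
  # a blob's low-contrast tail may touch the border even when the molecule
  # is well inside, so the border criterion applies to the localization,
  # not to the region footprint
  m <- cfg$edge_margin_px
  if (m > 0) {
    H <- nrow(labels); W <- ncol(labels)
    keep <- out$x_px >= m & out$x_px <= W - m &
            out$y_px >= m & out$y_px <= H - m
    out <- out[keep, , drop = FALSE]
  }
  out
}

# Separable running-max filter with Chebyshev radius r (r unit dilations
# per axis).
local_max_filter <- function(img, r) {
  dilate1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    if (n < 2) return(m)
    out <- m
    if (along_rows) {
      out[2:n, ] <- pmax(out[2:n, ], m[1:(n - 1), ])
      out[1:(n - 1), ] <- pmax(out[1:(n - 1), ], m[2:n, ])
    } else {
      out[, 2:n] <- pmax(out[, 2:n], m[, 1:(n - 1)])
      out[, 1:(n - 1)] <- pmax(out[, 1:(n - 1)], m[, 2:n])
    }
    out
  }
  for (d in seq_len(r)) img <- dilate1(img, TRUE)
  for (d in seq_len(r)) img <- dilate1(img, FALSE)
  img
}

# Split each labeled region between its intensity peaks (local maxima of the
# smoothed image separated by >= peak_min_sep_px); pixels go to the nearest
# peak. Regions with a single peak are left intact.
split_regions_at_peaks <- function(fa, seg, cfg) {
  r <- cfg$peak_min_sep_px
  if (r <= 0 || length(seg$ids) == 0) return(seg$labels)
  mx <- local_max_filter(fa, r)
  labels <- seg$labels
  next_label <- max(labels)
  for (id in seg$ids) {
    sel <- which(labels == id, arr.ind = TRUE)
    is_peak <- fa[sel] >= mx[sel] - 1e-15
    if (sum(is_peak) <= 1) next
    pk <- sel[is_peak, , drop = FALSE]
    # non-maximum suppression: plateau ties produce adjacent "peaks"; keep
    # one representative per cluster closer than the separation radius
    ord <- order(-fa[pk], pk[, 2], pk[, 1])
    keep <- integer(0)
    for (i in ord) {
      if (all(pmax(abs(pk[keep, 1] - pk[i, 1]),
                   abs(pk[keep, 2] - pk[i, 2])) > r) || !length(keep))
        keep <- c(keep, i)
    }
    pk <- pk[sort(keep), , drop = FALSE]
    if (nrow(pk) <= 1) next
    # nearest-peak assignment
    d2 <- outer(sel[, 1], pk[, 1], "-")^2 + outer(sel[, 2], pk[, 2], "-")^2
    assign <- max.col(-d2, ties.method = "first")
    keep_sizes <- tabulate(assign, nbins = nrow(pk))
    for (k in seq_len(nrow(pk))) {
      if (keep_sizes[k] < cfg$min_area_px) next
      new_id <- if (k == 1) id else { next_label <- next_label + 1L; next_label }
      rows <- sel[assign == k, , drop = FALSE]
      labels[rows] <- new_id
    }
    # undersized fragments are removed
    small <- which(keep_sizes < cfg$min_area_px)
    for (k in small) labels[sel[assign == k, , drop = FALSE]] <- 0L
  }
  labels
}

empty_localizations <- function() {
  data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
             x_nm = numeric(0), y_nm = numeric(0), area_px = integer(0),
             mean_abs_contrast = numeric(0), label = integer(0))
}

#' Detect blobs in every frame of a contrast stack
#'
#' @param cstack A `contrast_stack`.
#' @param cfg A [detection_config()]; if `NULL`, a default configuration is
#'   built with [estimate_threshold()].
#' @return Localization data frame; `frame` refers to raw movie frames.
#' @export
detect_stack <- function(cstack, cfg = NULL) {
  if (is.null(cfg)) cfg <- detection_config(estimate_threshold(cstack))
  nt <- dim(cstack$frames)[3]
  out <- lapply(seq_len(nt), function(t)
    detect_frame(cstack$frames[, , t], cfg, cstack$pixel_nm,
                 frame = cstack$raw_frame_index[t]))
  res <- do.call(rbind, out)
  if (is.null(res)) empty_localizations() else res
}
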