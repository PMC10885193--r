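#' Lane-relative binding-site histogram
#'
#' Projects localization positions onto the cross-lane axis (signed
#' coordinate along the lane normal) or the along-lane axis and bins them.
#' Peaks are local maxima of a 3-bin moving average that exceed the global
#' median bin count; on lane-patterned surfaces the cross-lane peaks sit a
#' few hundred nanometres inside the trenches, offset from the edges by
#' about the coil radius.
#'
#' @param locs Localization data frame (`x_nm`, `y_nm`).
#' @param surface A [surface_model()] providing `lane_axis` and
#'   `lane_edges_x`.
#' @param bin_nm Bin width in nm (default 100, so peak offsets of a few
#'   hundred nm span several bins).
#' @param axis `"cross"` (default) or `"along"`.
#' @return An object of class `spatial_histogram`: `axis`, `bin_edges_nm`,
#'   `counts`, `mids_nm`, `peak_positions_nm`, `reference_edges_nm`, `n`.
#' @export
lane_histogram <- function(locs, surface, bin_nm = 100,
                           axis = c("cross", "along")) {
  axis <- match.arg(axis)
  check_scalar_pos(bin_nm, "bin_nm")
  u <- if (axis == "along") surface$lane_axis else lane_normal(surface$lane_axis)
  coord <- locs$x_nm * u[1] + locs$y_nm * u[2]
  if (length(coord) == 0) {
    return(structure(list(axis = axis, bin_edges_nm = numeric(0),
                          counts = integer(0), mids_nm = numeric(0),
                          peak_positions_nm = numeric(0),
                          reference_edges_nm = surface$lane_edges_x, n = 0L),
                     class = "spatial_histogram"))
  }
  lo <- floor(min(coord) / bin_nm) * bin_nm
  hi <- ceiling(max(coord) / bin_nm) * bin_nm
  if (hi <= lo) hi <- lo + bin_nm
  edges <- seq(lo, hi, by = bin_nm)
  counts <- as.integer(table(cut(coord, edges, include.lowest = TRUE,
                                 right = FALSE)))
  mids <- edges[-length(edges)] + bin_nm / 2
  structure(list(axis = axis, bin_edges_nm = edges, counts = counts,
                 mids_nm = mids,
                 peak_positions_nm = find_peaks(counts, mids),
                 reference_edges_nm = if (axis == "cross")
                   surface$lane_edges_x else numeric(0),
                 n = length(coord)),
            class = "spatial_histogram")
}

# Local maxima of the 3-bin moving average exceeding the global median count.
find_peaks <- function(counts, mids) {
  k <- length(counts)
  if (k < 3) return(if (k >= 1) mids[which.max(counts)][counts[which.max(counts)] > 0] else numeric(0))
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(counts[1:2]); sm[k] <- mean(counts[(k - 1):k])
  thr <- median(counts)
  is_peak <- vapply(seq_len(k), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < k) sm[i + 1] else -Inf
    sm[i] > thr && sm[i] >= left && sm[i] > right
  }, TRUE)
  mids[is_peak]
}

#' @export
print.spatial_histogram <- function(x, ...) {
  cat(sprintf("spatial_histogram (%s-lane): %d localizations in %d bins, %d peak(s)\n",
              x$axis, x$n, length(x$counts), length(x$peak_positions_nm)))
  invisible(x)
}

#' Peak offsets from the nearest lane edge
#'
#' @param hist A cross-lane [lane_histogram()].
#' @return Data frame: `peak_nm`, `nearest_edge_nm`, `offset_nm`
#'   (absolute distance), one row per detected peak; also reported pooled
#'   over edges via the `offset_nm` column itself (offsets are per-peak;
#'   summarise as needed).
#' @export
peak_edge_offsets <- function(hist) {
  if (length(hist$reference_edges_nm) == 0 ||
      length(hist$peak_positions_nm) == 0)
    return(data.frame(peak_nm = numeric(0), nearest_edge_nm = numeric(0),
                      offset_nm = numeric(0)))
  nearest <- vapply(hist$peak_positions_nm, function(p)
    hist$reference_edges_nm[which.min(abs(hist$reference_edges_nm - p))], 0)
  data.frame(peak_nm = hist$peak_positions_nm, nearest_edge_nm = nearest,
             offset_nm = abs(hist$peak_positions_nm - nearest))
}

#' Contrast-bias control across the lane profile
#'
#' If localizations near lane edges systematically carried stronger
#' absolute contrast, apparent edge accumulation could be a detection
#' artefact. This control bins localizations along the cross-lane axis and
#' tests the per-bin `mean_abs_contrast` values for heterogeneity with a
#' rank-based one-way (Kruskal-Wallis) test.
#'
#' @inheritParams lane_histogram
#' @return A list: `mids_nm`, `mean_abs_contrast` (per-bin mean), `n_bins`
#'   (occupied), `p_value`, `bias_suspected` (`p < 0.01`).
#' @export
contrast_bias_check <- function(locs, surface, bin_nm = 100) {
  check_scalar_pos(bin_nm, "bin_nm")
  u <- lane_normal(surface$lane_axis)
  coord <- locs$x_nm * u[1] + locs$y_nm * u[2]
  bin <- floor(coord / bin_nm)
  occupied <- sort(unique(bin))
  prof <- vapply(occupied, function(b)
    mean(locs$mean_abs_contrast[bin == b]), 0)
  if (length(occupied) < 2) {
    warning("contrast_bias_check: fewer than 2 occupied bins; heterogeneity undefined")
    return(list(mids_nm = (occupied + 0.5) * bin_nm,
                mean_abs_contrast = prof, n_bins = length(occupied),
                p_value = NA_real_, bias_suspected = FALSE))
  }
  p <- kruskal.test(locs$mean_abs_contrast, factor(bin))$p.value
  list(mids_nm = (occupied + 0.5) * bin_nm, mean_abs_contrast = prof,
       n_bins = length(occupied), p_value = p,
       bias_suspected = is.finite(p) && p < 0.01)
}

#' Decomposed mean squared displacement
#'
#' MSD at lag `tau` is the mean over all ordered within-trajectory pairs
#' separated by `tau` frames of the squared displacement, decomposed into
#' components along the lane axis and perpendicular to it. By Pythagoras
#' the two components sum to the total at every lag.
#'
#' @param trajs Trajectory data frame (`trajectory_id`, `frame`, `x_nm`,
#'   `y_nm`), e.g. the `trajectories` element of [link_localizations()].
#' @param lane_axis Unit 2-vector.
#' @param max_lag Largest lag in frames (default: longest trajectory span).
#' @return Data frame of class `msd_curve`: `lag_frames`, `msd_total_nm2`,
#'   `msd_along_nm2`, `msd_perp_nm2`, `n_pairs` (lag 0 included, MSD 0).
#' @export
msd_decomposed <- function(trajs, lane_axis, max_lag = NULL) {
  u <- lane_axis / sqrt(sum(lane_axis^2))
  v <- lane_normal(u)
  by_traj <- split(trajs[, c("frame", "x_nm", "y_nm")], trajs$trajectory_id)
  if (is.null(max_lag)) {
    spans <- vapply(by_traj, function(d) diff(range(d$frame)), 0)
    max_lag <- if (length(spans)) max(spans) else 0
  }
  lags <- seq_len(max_lag)
  along2 <- perp2 <- total2 <- numeric(length(lags))
  npairs <- integer(length(lags))
  for (d in by_traj) {
    d <- d[order(d$frame), , drop = FALSE]
    for (li in seq_along(lags)) {
      tau <- lags[li]
      j <- match(d$frame + tau, d$frame)
      ok <- !is.na(j)
      if (!any(ok)) next
      dx <- d$x_nm[j[ok]] - d$x_nm[ok]
      dy <- d$y_nm[j[ok]] - d$y_nm[ok]
      pa <- dx * u[1] + dy * u[2]
      pp <- dx * v[1] + dy * v[2]
      along2[li] <- along2[li] + sum(pa^2)
      perp2[li] <- perp2[li] + sum(pp^2)
      total2[li] <- total2[li] + sum(dx^2 + dy^2)
      npairs[li] <- npairs[li] + sum(ok)
    }
  }
  keep <- npairs > 0
  out <- data.frame(lag_frames = c(0L, lags[keep]),
                    msd_total_nm2 = c(0, total2[keep] / npairs[keep]),
                    msd_along_nm2 = c(0, along2[keep] / npairs[keep]),
                    msd_perp_nm2 = c(0, perp2[keep] / npairs[keep]),
                    n_pairs = c(NA_integer_, npairs[keep]))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Step angles and axial isotropy test
#'
#' Angles of per-frame displacement vectors relative to the lane axis, in
#' (-pi, pi]. Lane-guided motion would be bidirectional (back and forth
#' along the lanes), so isotropy is assessed with the Rayleigh test on
#' doubled angles (axial data): a significant resultant of `2 * theta`
#' indicates a preferred axis even when the two directions along it are
#' balanced.
#'
#' @inheritParams msd_decomposed
#' @return A list: `angles_rad`, `n`, `resultant_length` (mean resultant of
#'   the doubled angles), `p_value` (Rayleigh). Zero-length steps are
#'   excluded; if no nonzero steps remain the statistic is `NA` with a
#'   warning.
#' @export
step_angles <- function(trajs, lane_axis) {
  u <- lane_axis / sqrt(sum(lane_axis^2))
  v <- lane_normal(u)
  by_traj <- split(trajs[, c("frame", "x_nm", "y_nm")], trajs$trajectory_id)
  ang <- unlist(lapply(by_traj, function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    if (nrow(d) < 2) return(numeric(0))
    j <- match(d$frame + 1L, d$frame)
    ok <- !is.na(j)
    dx <- d$x_nm[j[ok]] - d$x_nm[ok]
    dy <- d$y_nm[j[ok]] - d$y_nm[ok]
    atan2(dx * v[1] + dy * v[2], dx * u[1] + dy * u[2])[dx != 0 | dy != 0]
  }), use.names = FALSE)
  if (length(ang) == 0) {
    warning("step_angles: no nonzero steps; isotropy statistic undefined")
    return(list(angles_rad = numeric(0), n = 0L,
                resultant_length = NA_real_, p_value = NA_real_))
  }
  list(angles_rad = ang, n = length(ang),
       resultant_length = rayleigh_test(2 * ang)$rbar,
       p_value = rayleigh_test(2 * ang)$p_value)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of uniformly distributed angles against a unimodal
#' alternative using the mean resultant length, with the standard
#' finite-sample correction to the `exp(-Z)` tail approximation.
#'
#' @param angles_rad Angles in radians.
#' @return A list: `rbar` (mean resultant length), `z` (`n * rbar^2`),
#'   `p_value`.
#' @export
rayleigh_test <- function(angles_rad) {
  n <- length(angles_rad)
  if (n == 0) return(list(rbar = NA_real_, z = NA_real_, p_value = NA_real_))
  C <- sum(cos(angles_rad)); S <- sum(sin(angles_rad))
  rbar <- sqrt(C^2 + S^2) / n
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(rbar = rbar, z = z, p_value = min(max(p, 0), 1))
}

#' Chi-square test of histogram uniformity
#'
#' @param hist A [lane_histogram()] (typically along-lane).
#' @return p-value of `chisq.test` against equal expected counts, `NA` for
#'   fewer than 2 bins.
#' @export
histogram_uniformity <- function(hist) {
  if (length(hist$counts) < 2) return(NA_real_)
  suppressWarnings(chisq.test(hist$counts)$p.value)
}
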