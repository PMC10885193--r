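#' Surface model: binding-affinity map plus lane geometry
#'
#' Couples a per-pixel relative binding-affinity map to the static
#' scattering background and (optionally) the geometry of etched lanes.
#' The simulator draws landing positions with probability proportional to
#' `affinity`; the spatial statistics use `lane_edges_x` / `lane_axis` to
#' compute lane-relative coordinates.
#'
#' @param affinity `H x W` matrix of non-negative relative binding weights.
#' @param background_template `H x W` matrix of static scattering
#'   intensities (camera counts); must be positive wherever contrast is to
#'   be evaluated.
#' @param pixel_nm Pixel pitch in nm.
#' @param lane_edges_x Strictly increasing positions (nm) of lane edges
#'   along the cross-lane axis; `numeric(0)` when the surface has no lanes.
#' @param lane_axis Unit 2-vector giving the along-lane direction
#'   (default `c(0, 1)`: lanes run along y, edges are vertical lines).
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(affinity, background_template, pixel_nm,
                          lane_edges_x = numeric(0), lane_axis = c(0, 1)) {
  if (!is.matrix(affinity) || anyNA(affinity) || any(affinity < 0))
    stop_invalid("affinity must be a matrix of finite non-negative weights")
  if (!is.matrix(background_template) ||
      !all(dim(background_template) == dim(affinity)))
    stop_invalid("background_template must match affinity dimensions")
  if (any(background_template < 0))
    stop_invalid("background_template must be non-negative")
  check_scalar_pos(pixel_nm, "pixel_nm")
  if (length(lane_edges_x) > 1 && any(diff(lane_edges_x) <= 0))
    stop_invalid("lane_edges_x must be strictly increasing")
  nrm <- sqrt(sum(lane_axis^2))
  if (length(lane_axis) != 2L || !is.finite(nrm) || nrm == 0)
    stop_invalid("lane_axis must be a nonzero 2-vector")
  structure(list(affinity = affinity,
                 background_template = background_template,
                 pixel_nm = pixel_nm,
                 lane_edges_x = lane_edges_x,
                 lane_axis = lane_axis / nrm),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("surface_model: %d x %d px (%.0f nm/px), %d lane edges\n",
              nrow(x$affinity), ncol(x$affinity), x$pixel_nm,
              length(x$lane_edges_x)))
  invisible(x)
}

#' Uniform (pristine) surface
#'
#' Flat scattering background and spatially uniform binding affinity, the
#' model of an unpatterned hBN flake. An optional dead margin sets affinity
#' to zero within `margin_nm` of the field-of-view border, which keeps
#' simulated molecules away from the edge (useful when studying kinetics
#' without censoring by field-of-view exits).
#'
#' @param n_px Image side length in pixels (square field of view).
#' @param pixel_nm Pixel pitch in nm.
#' @param bg_level Background intensity in camera counts (default 1000).
#' @param margin_nm Width of the zero-affinity border band (default 0).
#' @return A [surface_model()].
#' @export
surface_uniform <- function(n_px, pixel_nm = 33, bg_level = 1000,
                            margin_nm = 0) {
  aff <- matrix(1, n_px, n_px)
  if (margin_nm > 0) {
    m <- ceiling(margin_nm / pixel_nm)
    if (2 * m >= n_px) stop_invalid("margin_nm leaves no binding area")
    keep <- (m + 1):(n_px - m)
    aff[,] <- 0
    aff[keep, keep] <- 1
  }
  surface_model(aff, matrix(bg_level, n_px, n_px), pixel_nm)
}

#' Surface with a defect-rich square
#'
#' Emulates a focused-ion-beam milled square: binding affinity inside the
#' square is multiplied by `boost` relative to the pristine surround. The
#' background is flat (the etched area images at nearly the same level as
#' the surround).
#'
#' @inheritParams surface_uniform
#' @param side_nm Side length of the square (nm).
#' @param boost Affinity multiplier inside the square (default 3).
#' @return A [surface_model()].
#' @export
surface_defect_square <- function(n_px, pixel_nm = 33, bg_level = 1000,
                                  side_nm = 1500, boost = 3) {
  s <- surface_uniform(n_px, pixel_nm, bg_level)
  centers <- (seq_len(n_px) - 0.5) * pixel_nm
  mid <- n_px * pixel_nm / 2
  inside <- abs(centers - mid) <= side_nm / 2
  s$affinity[inside, inside] <- boost
  s
}

#' Surface with etched lanes and edge-enhanced binding
#'
#' Emulates a lane-patterned flake: parallel trenches of width
#' `lane_width_nm` separated by mesas of the same width, with lanes running
#' along `lane_axis` (default y). Lane edges scatter more strongly, which is
#' modelled as Gaussian intensity ridges on the background template. Binding
#' affinity is a pristine baseline plus Gaussian enhancement ridges placed
#' `edge_offset_nm` inside each trench from both of its edges, reproducing
#' the accumulation of binding a few hundred nanometres inside the trenches.
#'
#' @inheritParams surface_uniform
#' @param lane_width_nm Trench (and mesa) width in nm (default 1000).
#' @param first_edge_nm Cross-lane position of the first trench edge
#'   (default 700 nm).
#' @param edge_offset_nm Offset of the affinity peaks from the trench edges,
#'   into the trench (default 300 nm). Set `edge_boost = 0` for lanes whose
#'   binding is uniform.
#' @param edge_boost Peak affinity enhancement relative to baseline 1
#'   (default 4).
#' @param ridge_sigma_nm Width of both the affinity and the background
#'   ridges (default 60 nm).
#' @param edge_brightness Relative intensity elevation of the background at
#'   the lane edges (default 0.3).
#' @return A [surface_model()] with `lane_edges_x` filled in.
#' @export
surface_lanes <- function(n_px, pixel_nm = 33, bg_level = 1000,
                          lane_width_nm = 1000, first_edge_nm = 700,
                          edge_offset_nm = 300, edge_boost = 4,
                          ridge_sigma_nm = 60, edge_brightness = 0.3) {
  fov <- n_px * pixel_nm
  edges <- seq(first_edge_nm, fov - 1, by = lane_width_nm)
  edges <- edges[edges > 0 & edges < fov]
  x <- (seq_len(n_px) - 0.5) * pixel_nm  # cross-lane pixel centres
  bg_prof <- rep(1, n_px)
  aff_prof <- rep(1, n_px)
  # odd-indexed edges open a trench, even-indexed close it
  for (i in seq_along(edges)) {
    bg_prof <- bg_prof +
      edge_brightness * exp(-(x - edges[i])^2 / (2 * ridge_sigma_nm^2))
    into <- if (i %% 2 == 1) edges[i] + edge_offset_nm
            else edges[i] - edge_offset_nm
    aff_prof <- aff_prof +
      edge_boost * exp(-(x - into)^2 / (2 * ridge_sigma_nm^2))
  }
  # profiles vary along the cross-lane (x, column) axis, constant along y
  aff <- matrix(aff_prof, n_px, n_px, byrow = TRUE)
  bg <- matrix(bg_level * bg_prof, n_px, n_px, byrow = TRUE)
  surface_model(aff, bg, pixel_nm, lane_edges_x = edges, lane_axis = c(0, 1))
}

# Cross-lane unit normal (so that for lanes along y the cross coordinate is x).
lane_normal <- function(lane_axis) c(lane_axis[2], -lane_axis[1])
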