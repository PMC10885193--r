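mk_traj <- function(id, frames, x, y) {
  data.frame(trajectory_id = id, frame = frames, x_nm = x, y_nm = y)
}

test_that("MSD decomposition: trivial cases and the Pythagorean identity", {
  # stationary trajectory
  tr <- mk_traj(1, 1:5, rep(100, 5), rep(200, 5))
  m <- msd_decomposed(tr, c(0, 1))
  expect_true(all(m$msd_total_nm2 == 0))

  # straight line along x, axis = x
  tr2 <- mk_traj(1, 1:3, c(0, 1, 2), c(0, 0, 0))
  m2 <- msd_decomposed(tr2, c(1, 0))
  expect_equal(m2$msd_along_nm2[m2$lag_frames == 1], 1)
  expect_equal(m2$msd_along_nm2[m2$lag_frames == 2], 4)
  expect_true(all(m2$msd_perp_nm2 == 0))
  expect_equal(m2$msd_total_nm2[1], 0)  # lag 0

  # random trajectories, arbitrary axis: total = along + perp to 1e-9
  set.seed(14)
  trs <- do.call(rbind, lapply(1:6, function(id)
    mk_traj(id, 1:10, cumsum(rnorm(10, 0, 50)), cumsum(rnorm(10, 0, 50)))))
  ang <- runif(1, 0, 2 * pi)
  m3 <- msd_decomposed(trs, c(cos(ang), sin(ang)))
  expect_equal(m3$msd_total_nm2, m3$msd_along_nm2 + m3$msd_perp_nm2,
               tolerance = 1e-9)
})

test_that("MSD of isotropic Brownian motion matches 2 D tau per component", {
  set.seed(99)
  D <- 0.05; dt <- 1 / 90.5
  step_sd <- sqrt(2 * D * dt) * 1000  # nm per axis
  trs <- do.call(rbind, lapply(1:300, function(id)
    mk_traj(id, 1:12, cumsum(c(0, rnorm(11, 0, step_sd))),
            cumsum(c(0, rnorm(11, 0, step_sd))))))
  m <- msd_decomposed(trs, c(0, 1), max_lag = 4)
  for (lag in 1:4) {
    row <- m[m$lag_frames == lag, ]
    expected <- 2 * D * 1e6 * dt * lag  # nm^2
    se <- expected * sqrt(2 / row$n_pairs) * 2  # rough SE of a chi-square mean
    expect_lt(abs(row$msd_along_nm2 - expected), 3 * se)
    expect_lt(abs(row$msd_perp_nm2 - expected), 3 * se)
    expect_equal(row$msd_total_nm2, row$msd_along_nm2 + row$msd_perp_nm2,
                 tolerance = 1e-9)
  }
})

test_that("spatial statistics are invariant under joint rotation", {
  set.seed(25)
  trs <- do.call(rbind, lapply(1:5, function(id)
    mk_traj(id, 1:8, cumsum(rnorm(8, 0, 40)) + 500,
            cumsum(rnorm(8, 0, 40)) + 500)))
  axis0 <- c(0, 1)
  m0 <- msd_decomposed(trs, axis0)
  th <- 0.77
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- trs
  xy <- as.matrix(trs[, c("x_nm", "y_nm")]) %*% t(R)
  rot$x_nm <- xy[, 1]; rot$y_nm <- xy[, 2]
  m1 <- msd_decomposed(rot, as.vector(R %*% axis0))
  expect_equal(m0$msd_along_nm2, m1$msd_along_nm2, tolerance = 1e-9)
  expect_equal(m0$msd_perp_nm2, m1$msd_perp_nm2, tolerance = 1e-9)
})

test_that("step angles: axial alignment and the doubled-angle statistic", {
  # all steps along +x with axis x: perfectly axial
  tr <- mk_traj(1, 1:6, cumsum(rep(50, 6)), rep(0, 6))
  sa <- step_angles(tr, c(1, 0))
  expect_equal(sa$resultant_length, 1, tolerance = 1e-12)
  expect_lt(sa$p_value, 0.05)

  # steps at +90 and -90 degrees: doubled angles coincide
  tr2 <- mk_traj(1, 1:3, c(0, 0, 0), c(0, 50, 0))
  sa2 <- step_angles(tr2, c(1, 0))
  expect_equal(sort(sa2$angles_rad), c(-pi / 2, pi / 2))
  expect_equal(sa2$resultant_length, 1, tolerance = 1e-12)

  # all-zero steps: undefined with a warning
  tr3 <- mk_traj(1, 1:4, rep(5, 4), rep(5, 4))
  expect_warning(sa3 <- step_angles(tr3, c(1, 0)))
  expect_true(is.na(sa3$p_value))
})

test_that("Rayleigh test calibrates on isotropic steps", {
  reject <- 0
  for (s in 1:100) {
    set.seed(500 + s)
    ang <- runif(2000, -pi, pi)
    if (rayleigh_test(2 * ang)$p_value <= 0.01) reject <- reject + 1
  }
  expect_lte(reject, 5)
  # and detects a strongly axial sample
  set.seed(1)
  axial <- c(rnorm(500, 0, 0.2), rnorm(500, pi, 0.2))
  expect_lt(rayleigh_test(2 * axial)$p_value, 1e-6)
})

test_that("lane histogram: degenerate and uniform cases", {
  surf <- surface_lanes(103, 33)
  # all localizations at one coordinate fall in a single bin
  locs1 <- data.frame(x_nm = rep(505, 40), y_nm = runif(40, 0, 3000))
  h1 <- lane_histogram(locs1, surf, bin_nm = 100, axis = "cross")
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(sum(h1$counts), 40)

  # uniform along-lane positions pass a chi-square uniformity check
  set.seed(31)
  locs2 <- data.frame(x_nm = runif(3000, 0, 3399), y_nm = runif(3000, 0, 3399))
  h2 <- lane_histogram(locs2, surf, bin_nm = 100, axis = "along")
  expect_equal(sum(h2$counts), 3000)
  expect_gt(histogram_uniformity(h2), 0.01)

  # empty input: empty histogram, not an error
  h0 <- lane_histogram(locs2[0, ], surf, 100, "cross")
  expect_equal(h0$n, 0)
})

test_that("affinity peaks offset into the trenches are recovered within one bin", {
  surf <- surface_lanes(103, 33, edge_offset_nm = 300)
  set.seed(8)
  # draw localizations from the surface's own cross-lane affinity profile
  prof <- surf$affinity[1, ]  # affinity varies along columns (cross-lane x)
  cols <- sample(seq_along(prof), 8000, replace = TRUE, prob = prof)
  locs <- data.frame(x_nm = (cols - 1 + runif(8000)) * 33,
                     y_nm = runif(8000, 0, 3399))
  h <- lane_histogram(locs, surf, bin_nm = 100, axis = "cross")
  off <- peak_edge_offsets(h)
  expect_gt(nrow(off), 0)
  # every detected peak sits 300 nm from its nearest edge, within one bin
  expect_true(all(abs(off$offset_nm - 300) <= 100))
  # and peaks are found near most edges
  expect_gte(nrow(off), length(surf$lane_edges_x) - 1)
})

test_that("contrast-bias control: null, adversarial, and degenerate inputs", {
  surf <- surface_lanes(103, 33)
  trench <- function(x) {
    e <- surf$lane_edges_x
    inside <- rep(FALSE, length(x))
    for (i in seq(1, length(e) - 1, by = 2))
      inside <- inside | (x >= e[i] & x <= e[i + 1])
    inside
  }
  flagged <- 0
  for (s in 1:30) {
    set.seed(600 + s)
    locs <- data.frame(x_nm = runif(800, 0, 3399), y_nm = runif(800, 0, 3399),
                       mean_abs_contrast = rexp(800, 20))
    if (contrast_bias_check(locs, surf, 100)$bias_suspected)
      flagged <- flagged + 1
  }
  expect_lte(flagged, 2)

  set.seed(9)
  locs <- data.frame(x_nm = runif(2000, 0, 3399), y_nm = runif(2000, 0, 3399),
                     mean_abs_contrast = rexp(2000, 20))
  locs$mean_abs_contrast[trench(locs$x_nm)] <-
    2 * locs$mean_abs_contrast[trench(locs$x_nm)]
  expect_true(contrast_bias_check(locs, surf, 100)$bias_suspected)

  one_bin <- data.frame(x_nm = rep(150, 5), y_nm = 1:5,
                        mean_abs_contrast = rexp(5, 20))
  expect_warning(res <- contrast_bias_check(one_bin, surf, 100))
  expect_false(res$bias_suspected)
  expect_true(is.na(res$p_value))
})

test_that("histogram counts are invariant to translation along the lane axis", {
  surf <- surface_lanes(103, 33)
  set.seed(3)
  locs <- data.frame(x_nm = runif(500, 200, 3000), y_nm = runif(500, 0, 3399))
  h1 <- lane_histogram(locs, surf, 100, "cross")
  locs2 <- locs; locs2$y_nm <- locs2$y_nm + 917  # shift along the lanes
  h2 <- lane_histogram(locs2, surf, 100, "cross")
  expect_equal(h1$counts, h2$counts)
  expect_equal(h1$peak_positions_nm, h2$peak_positions_nm)
})
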