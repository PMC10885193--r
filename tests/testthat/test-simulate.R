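test_that("event sampling and rendering are bit-reproducible under a seed", {
  cfg <- sim_config(n_frames = 40, arrival_rate = 0.3, seed = 123)
  surf <- surface_uniform(24, 33)
  t1 <- sample_events(cfg, surf)
  t2 <- sample_events(cfg, surf)
  expect_identical(t1, t2)
  m1 <- render_movie(cfg, surf, t1)
  m2 <- render_movie(cfg, surf, t2)
  expect_identical(m1$frames, m2$frames)
  t3 <- sample_events(cfg, surf, seed = 124)
  expect_false(identical(truth_table(t1), truth_table(t3)))
})

test_that("zero arrival rate yields no events; zero affinity errors", {
  cfg <- sim_config(n_frames = 50, arrival_rate = 0)
  surf <- surface_uniform(16, 33)
  expect_length(sample_events(cfg, surf), 0)

  cfg2 <- sim_config(n_frames = 50, arrival_rate = 1)
  surf2 <- surf
  surf2$affinity[] <- 0
  expect_error(sample_events(cfg2, surf2), class = "iscattrack_invalid")
})

test_that("landings follow the affinity map support", {
  cfg <- sim_config(n_frames = 200, arrival_rate = 1, seed = 5)
  surf <- surface_uniform(16, 33)
  surf$affinity[] <- 0
  surf$affinity[7, 11] <- 1  # row 7, col 11 (1-based)
  ev <- sample_events(cfg, surf)
  expect_gt(length(ev), 100)
  x0 <- vapply(ev, function(p) p$x_nm[1], 0)
  y0 <- vapply(ev, function(p) p$y_nm[1], 0)
  expect_true(all(floor(x0 / 33) == 10))
  expect_true(all(floor(y0 / 33) == 6))
})

test_that("event count concentrates at the Poisson mean", {
  cfg <- sim_config(n_frames = 500, arrival_rate = 2, seed = 77,
                    mean_dwell_ms = 20, diffusion_um2_s = 0)
  surf <- surface_uniform(32, 33)
  n <- length(sample_events(cfg, surf))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
})

test_that("continuous dwell draws average to the configured mean", {
  cfg <- sim_config(n_frames = 4000, arrival_rate = 3, seed = 11,
                    diffusion_um2_s = 0, mean_dwell_ms = 50)
  surf <- surface_uniform(40, 33, margin_nm = 200)
  ev <- sample_events(cfg, surf)
  d <- vapply(ev, function(p) p$dwell_ms_true, 0)
  expect_gt(length(d), 10000)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 50), 3 * se)
  # discretisation: ceiling to frames, minimum one frame
  nf <- vapply(ev, function(p) p$dwell_frames_drawn, 0L)
  expect_true(all(nf == pmax(1, ceiling(d / frame_period_ms(90.5)))))
})

test_that("per-axis MSD of simulated motion matches 2 D tau", {
  D <- 0.05; rate <- 90.5
  cfg <- sim_config(n_frames = 2000, arrival_rate = 0.5, seed = 19,
                    diffusion_um2_s = D, mean_dwell_ms = 200,
                    fov_um = 33 * 200 / 1000, pixel_nm = 33)
  # huge FOV so boundary truncation never bites
  surf <- surface_uniform(200, 33, margin_nm = 2000)
  ev <- sample_events(cfg, surf)
  steps_x <- unlist(lapply(ev, function(p) diff(p$x_nm)))
  expect_gt(length(steps_x), 3000)
  msd1 <- mean(steps_x^2)                     # nm^2 at lag 1
  expected <- 2 * D * 1e6 * (1 / rate) * 1000^2 / 1e6  # 2 D dt in nm^2
  se <- sd(steps_x^2) / sqrt(length(steps_x))
  expect_lt(abs(msd1 - expected), 3 * se)
})

test_that("axial offsets stay inside the configured spread", {
  cfg <- sim_config(n_frames = 500, arrival_rate = 0.5, seed = 2,
                    mean_dwell_ms = 150)
  surf <- surface_uniform(32, 33)
  ev <- sample_events(cfg, surf)
  z <- unlist(lapply(ev, function(p) p$z_nm))
  expect_true(all(abs(z) <= cfg$blob$axial_spread_nm / 2 + 1e-9))
})

test_that("field-of-view exit truncates the trajectory", {
  cfg <- sim_config(n_frames = 300, arrival_rate = 0.5, seed = 8,
                    diffusion_um2_s = 2, mean_dwell_ms = 500)
  surf <- surface_uniform(16, 33)  # tiny FOV, fast diffusion
  ev <- sample_events(cfg, surf)
  exited <- vapply(ev, function(p) p$exited_fov, TRUE)
  expect_gt(mean(exited), 0.3)
  fov <- 16 * 33
  for (p in ev) {
    expect_true(all(p$x_nm >= 0 & p$x_nm <= fov))
    expect_true(all(p$y_nm >= 0 & p$y_nm <= fov))
    expect_lte(p$dwell_frames, p$dwell_frames_drawn)
  }
})

test_that("rendering without particles or noise reproduces the background", {
  cfg <- sim_config(n_frames = 4, arrival_rate = 0, noise_sigma = 0)
  surf <- surface_lanes(40, 33)
  mov <- render_movie(cfg, surf, list())
  for (t in 1:4) expect_equal(mov$frames[, , t], surf$background_template)
})

test_that("K = 0 sub-scatterers is a configuration error", {
  expect_error(sim_config(blob = list(k_scatterers = 0)),
               class = "iscattrack_invalid")
})

test_that("rendered single-scatterer blob recovers the PSF width", {
  cfg <- sim_config(n_frames = 5, arrival_rate = 0, noise_sigma = 0,
                    blob = list(k_scatterers = 1, rg_nm = 0,
                                axial_spread_nm = 0, amplitude = 0.1,
                                phi0 = pi))  # cos(phi0) = -1: dark blob
  surf <- surface_uniform(41, 33)
  truth <- list(static_particle_truth(20.5 * 33, 20.5 * 33, 0, 4, 2))
  cs <- compute_contrast(render_movie(cfg, surf, truth), 3, "median")
  img <- abs(cs$frames[, , 2])
  tot <- sum(img)
  xs <- ((seq_len(41)) - 0.5) * 33
  mx <- sum(outer(rep(1, 41), xs) * img) / tot
  sx2 <- sum(outer(rep(1, 41), (xs - mx)^2) * img) / tot
  expect_equal(sqrt(sx2), cfg$blob$psf_sigma_nm, tolerance = 0.05)
  expect_equal(tot * 33^2, 0.1 * 2 * pi * 100^2, tolerance = 0.02)
})

test_that("detection scoring: exact, empty, and swap cases", {
  tt <- data.frame(frame = c(1, 1, 2), x_nm = c(100, 500, 300),
                   y_nm = c(100, 500, 300))
  sc <- score_detections(tt, tt, 50)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_equal(sc$rmse_nm, 0)

  sc2 <- score_detections(tt, tt[0, ], 50)
  expect_equal(sc2$recall, 0)
  expect_true(sc2$undefined)

  sc3 <- score_detections(tt[0, ], tt[0, ], 50)
  expect_equal(sc3$precision, 1)
  expect_equal(sc3$recall, 1)

  # two truths, two founds with a swap inside the radius: greedy matching
  # equals the brute-force optimal assignment on this instance
  t2 <- data.frame(frame = 1, x_nm = c(0, 100), y_nm = c(0, 0))
  f2 <- data.frame(frame = 1, x_nm = c(90, 10), y_nm = c(0, 0))
  sc4 <- score_detections(t2, f2, 200)
  bf <- brute_force_match(t2$x_nm, t2$y_nm, f2$x_nm, f2$y_nm, 200)
  expect_equal(sc4$n_matched, bf$links)
  expect_equal(sc4$rmse_nm, sqrt(bf$cost / bf$links))
})
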