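#' Simulation configuration
#'
#' Parameters of the synthetic iSCAT movie generator. The defaults emulate
#' the acquisition used for the 20 kbp dsDNA measurements: a 3.4 x 3.4 um
#' field of view imaged at 90.5 Hz, molecules arriving as a Poisson process,
#' dwelling for exponentially distributed times, diffusing laterally on the
#' surface and rendered as superpositions of signed interferometric
#' point-spread contributions spread over the polymer-coil footprint.
#'
#' @param fov_um Field-of-view side length in micrometres (default 3.4).
#' @param pixel_nm Pixel pitch in nm (default 33, giving a 103 x 103 px
#'   field at the default FOV).
#' @param frame_rate_hz Acquisition rate in Hz (default 90.5).
#' @param n_frames Number of frames to simulate.
#' @param arrival_rate Expected binding events per frame over the whole
#'   field of view (default 0.05, the event density of the pristine-surface
#'   measurements: roughly a thousand events per 30,000 frames).
#' @param mean_dwell_ms Mean of the exponential dwell-time distribution in
#'   ms (default 50).
#' @param diffusion_um2_s Lateral surface diffusion coefficient in um^2/s
#'   (default 0.05).
#' @param noise_sigma Pixel noise scale: per-pixel Gaussian noise with
#'   standard deviation `noise_sigma * sqrt(background)`, a Gaussian
#'   approximation to shot noise (default 0.4; with the default background
#'   of 1000 counts this is a contrast noise floor of ~0.013 RMS).
#' @param blob Rendering parameters, a list with elements
#'   `k_scatterers` (number of sub-scatterer point-spread contributions per
#'   molecule, default 68 — one per Kuhn segment of a 20 kbp chain),
#'   `psf_sigma_nm` (Gaussian PSF width, default
#'   100), `amplitude` (peak ratiometric contrast of one sub-scatterer,
#'   default 0.08), `wavelength_nm` (illumination wavelength, default 520),
#'   `n_medium` (refractive index of the medium, default 1.33, water),
#'   `rg_nm` (radius of the polymer-coil disk over which sub-scatterers are
#'   spread; default 337, a 20 kbp coil), `axial_spread_nm` (total axial
#'   extent of the coil and of the molecule's axial random walk, default
#'   500), `z_step_nm` (per-frame axial random-walk step, default 25), and
#'   `phi0` (reference interference phase, default 0).
#' @param seed Master seed fixing every stochastic draw (default 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fov_um = 3.4, pixel_nm = 33, frame_rate_hz = 90.5,
                       n_frames = 1000, arrival_rate = 0.05,
                       mean_dwell_ms = 50, diffusion_um2_s = 0.05,
                       noise_sigma = 0.4, blob = list(), seed = 1L) {
  check_scalar_pos(fov_um, "fov_um")
  check_scalar_pos(pixel_nm, "pixel_nm")
  check_scalar_pos(frame_rate_hz, "frame_rate_hz")
  if (!is.numeric(n_frames) || n_frames < 1) stop_invalid("n_frames must be >= 1")
  check_scalar_pos(arrival_rate, "arrival_rate", allow_zero = TRUE)
  check_scalar_pos(mean_dwell_ms, "mean_dwell_ms")
  check_scalar_pos(diffusion_um2_s, "diffusion_um2_s", allow_zero = TRUE)
  check_scalar_pos(noise_sigma, "noise_sigma", allow_zero = TRUE)
  b <- utils::modifyList(list(k_scatterers = 68L, psf_sigma_nm = 100,
                              amplitude = 0.08, wavelength_nm = 520,
                              n_medium = 1.33, rg_nm = 337,
                              axial_spread_nm = 500, z_step_nm = 25,
                              phi0 = 0), blob)
  if (b$k_scatterers < 1) stop_invalid("blob$k_scatterers must be >= 1")
  check_scalar_pos(b$psf_sigma_nm, "blob$psf_sigma_nm")
  check_scalar_pos(b$wavelength_nm, "blob$wavelength_nm")
  check_scalar_pos(b$n_medium, "blob$n_medium")
  check_scalar_pos(b$rg_nm, "blob$rg_nm", allow_zero = TRUE)
  check_scalar_pos(b$axial_spread_nm, "blob$axial_spread_nm", allow_zero = TRUE)
  structure(list(fov_um = fov_um, pixel_nm = pixel_nm,
                 frame_rate_hz = frame_rate_hz,
                 n_frames = as.integer(n_frames),
                 arrival_rate = arrival_rate, mean_dwell_ms = mean_dwell_ms,
                 diffusion_um2_s = diffusion_um2_s, noise_sigma = noise_sigma,
                 blob = b, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default surface for a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @param ... Passed to [surface_uniform()].
#' @return A uniform [surface_model()] matching the configured geometry.
#' @export
default_surface <- function(cfg, ...) {
  n_px <- round(cfg$fov_um * 1000 / cfg$pixel_nm)
  surface_uniform(n_px, cfg$pixel_nm, ...)
}

#' Sample ground-truth binding events
#'
#' Draws transient surface-binding events: arrivals are Poisson in time
#' (mean `arrival_rate` per frame), landing positions follow the surface
#' affinity map (uniform within the chosen pixel), dwell times are
#' exponential with mean `mean_dwell_ms` discretised to whole frames by
#' ceiling (every event occupies at least one frame), in-plane motion is an
#' isotropic Gaussian random walk with per-axis step variance
#' `2 * D * dt`, and the axial coordinate performs a reflected random walk
#' within the coil's axial spread. The field-of-view boundary is absorbing:
#' a molecule stepping outside is truncated at its last inside frame and
#' flagged `exited_fov`, the censoring mechanism that biases measured dwell
#' times downward.
#'
#' @param cfg A [sim_config()].
#' @param surface A [surface_model()]; its dimensions set the field of view.
#' @param seed Optional override of `cfg$seed`.
#' @return A list of `particle_truth` records with fields `particle_id`,
#'   `arrival_frame`, `dwell_frames` (observed frames), `dwell_frames_drawn`
#'   (before censoring), `dwell_ms_true` (continuous draw), `x_nm`, `y_nm`,
#'   `z_nm` (per-frame), and `exited_fov`.
#' @export
sample_events <- function(cfg, surface, seed = cfg$seed) {
  H <- nrow(surface$affinity); W <- ncol(surface$affinity)
  fov_x <- W * surface$pixel_nm; fov_y <- H * surface$pixel_nm
  if (cfg$arrival_rate > 0 && sum(surface$affinity) <= 0)
    stop_invalid("affinity map is all zero but arrival_rate > 0")
  dt_ms <- frame_period_ms(cfg$frame_rate_hz)
  step_sd_nm <- sqrt(2 * cfg$diffusion_um2_s * dt_ms / 1000) * 1000
  zmax <- cfg$blob$axial_spread_nm / 2

  with_seed(seed, {
    n_events <- rpois(1, cfg$arrival_rate * cfg$n_frames)
    if (n_events == 0) list() else {
    arrival <- sort(sample.int(cfg$n_frames, n_events, replace = TRUE))
    w <- as.vector(surface$affinity)
    pix <- sample.int(H * W, n_events, replace = TRUE, prob = w)
    row0 <- (pix - 1) %% H; col0 <- (pix - 1) %/% H
    x0 <- (col0 + runif(n_events)) * surface$pixel_nm
    y0 <- (row0 + runif(n_events)) * surface$pixel_nm
    dwell_ms <- rexp(n_events, rate = 1 / cfg$mean_dwell_ms)
    dwell_frames <- pmax(1L, as.integer(ceiling(dwell_ms / dt_ms)))
    lapply(seq_len(n_events), function(i) {
      nf <- dwell_frames[i]
      with_seed(derive_seed(seed, i, salt = 1L), {
        dx <- if (nf > 1) rnorm(nf - 1, 0, step_sd_nm) else numeric(0)
        dy <- if (nf > 1) rnorm(nf - 1, 0, step_sd_nm) else numeric(0)
        x <- x0[i] + cumsum(c(0, dx))
        y <- y0[i] + cumsum(c(0, dy))
        z <- numeric(nf)
        z[1] <- if (zmax > 0) runif(1, -zmax, zmax) else 0
        if (nf > 1) {
          dz <- rnorm(nf - 1, 0, cfg$blob$z_step_nm)
          for (t in 2:nf) {
            zt <- z[t - 1] + dz[t - 1]
            # reflect at the axial bounds
            if (zmax > 0) {
              while (zt > zmax || zt < -zmax) {
                if (zt > zmax) zt <- 2 * zmax - zt
                if (zt < -zmax) zt <- -2 * zmax - zt
              }
            } else zt <- 0
            z[t] <- zt
          }
        }
        inside <- x >= 0 & x <= fov_x & y >= 0 & y <= fov_y
        first_out <- match(FALSE, inside)
        exited <- !is.na(first_out)
        keep <- if (exited) seq_len(first_out - 1L) else seq_len(nf)
        # cap at movie end (not counted as an exit)
        keep <- keep[arrival[i] + keep - 1L <= cfg$n_frames]
        if (length(keep) == 0) return(NULL)
        structure(list(particle_id = i, arrival_frame = arrival[i],
                       dwell_frames = length(keep),
                       dwell_frames_drawn = nf,
                       dwell_ms_true = dwell_ms[i],
                       x_nm = x[keep], y_nm = y[keep], z_nm = z[keep],
                       exited_fov = exited),
                  class = "particle_truth")
      })
    }) |> Filter(f = Negate(is.null))
    }
  })
}

#' Ground truth as a per-frame data frame
#'
#' @param truth A list of `particle_truth` records from [sample_events()].
#' @return A data frame with one row per particle per frame: `particle_id`,
#'   `frame`, `x_nm`, `y_nm`, `z_nm`, `exited`.
#' @export
truth_table <- function(truth) {
  if (length(truth) == 0)
    return(data.frame(particle_id = integer(0), frame = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      z_nm = numeric(0), exited = logical(0)))
  do.call(rbind, lapply(truth, function(p) {
    data.frame(particle_id = p$particle_id,
               frame = p$arrival_frame + seq_len(p$dwell_frames) - 1L,
               x_nm = p$x_nm, y_nm = p$y_nm, z_nm = p$z_nm,
               exited = p$exited_fov)
  }))
}

#' Render a synthetic iSCAT movie
#'
#' Renders each frame as
#' `background * (1 + sum_particles sum_j a_j * G_sigma(r - r_j)) + noise`.
#' Each molecule is a rigid constellation of `k_scatterers` sub-scatterers
#' drawn once, uniformly within a disk of the coil's radius of gyration
#' (lateral, re-centred so the constellation's centre of mass is the
#' tracked position) and within the axial spread (z). Sub-scatterer `j`
#' contributes
#' a unit-peak Gaussian of width `psf_sigma_nm` with the signed amplitude
#' `a_j = amplitude * cos(phi0 + 4 * pi * n_medium * z_j / wavelength_nm)`,
#' so nanometric axial displacement inverts the contrast — the hallmark of
#' interferometric detection. Noise is zero-mean Gaussian with per-pixel
#' standard deviation `noise_sigma * sqrt(background)`; intensities are
#' clipped at zero.
#'
#' @inheritParams sample_events
#' @param truth Events from [sample_events()].
#' @return A [movie_stack()].
#' @export
render_movie <- function(cfg, surface, truth, seed = cfg$seed) {
  b <- cfg$blob
  if (b$k_scatterers < 1) stop_invalid("blob$k_scatterers must be >= 1")
  H <- nrow(surface$background_template); W <- ncol(surface$background_template)
  px <- surface$pixel_nm
  sigma <- b$psf_sigma_nm
  halfw <- ceiling(4 * sigma / px)
  xc <- (seq_len(W) - 0.5) * px
  yc <- (seq_len(H) - 0.5) * px
  phase_k <- 4 * pi * b$n_medium / b$wavelength_nm

  contrast <- array(0, c(H, W, cfg$n_frames))
  for (p in truth) {
    offs <- with_seed(derive_seed(seed, p$particle_id, salt = 2L), {
      r <- b$rg_nm * sqrt(runif(b$k_scatterers))
      th <- runif(b$k_scatterers, 0, 2 * pi)
      zs <- if (b$axial_spread_nm > 0)
        runif(b$k_scatterers, -b$axial_spread_nm / 2, b$axial_spread_nm / 2)
      else rep(0, b$k_scatterers)
      dx <- r * cos(th); dy <- r * sin(th)
      # the tracked position is the coil's centre of mass, about which Rg
      # is defined, so the constellation is re-centred on it
      list(dx = dx - mean(dx), dy = dy - mean(dy), dz = zs)
    })
    for (t in seq_len(p$dwell_frames)) {
      fr <- p$arrival_frame + t - 1L
      if (fr > cfg$n_frames) break
      amp <- b$amplitude * cos(b$phi0 + phase_k * (p$z_nm[t] + offs$dz))
      sx <- p$x_nm[t] + offs$dx
      sy <- p$y_nm[t] + offs$dy
      for (j in seq_len(b$k_scatterers)) {
        c0 <- floor(sx[j] / px - 0.5); r0 <- floor(sy[j] / px - 0.5)
        cols <- max(1, c0 - halfw + 1):min(W, c0 + halfw + 1)
        rows <- max(1, r0 - halfw + 1):min(H, r0 + halfw + 1)
        if (length(cols) == 0 || length(rows) == 0) next
        gx <- exp(-(xc[cols] - sx[j])^2 / (2 * sigma^2))
        gy <- exp(-(yc[rows] - sy[j])^2 / (2 * sigma^2))
        contrast[rows, cols, fr] <- contrast[rows, cols, fr] +
          amp[j] * (gy %o% gx)
      }
    }
  }

  frames <- array(0, c(H, W, cfg$n_frames))
  bg <- surface$background_template
  noise_sd <- cfg$noise_sigma * sqrt(bg)
  with_seed(derive_seed(seed, 0L, salt = 3L), {
    for (fr in seq_len(cfg$n_frames)) {
      f <- bg * (1 + contrast[, , fr])
      if (cfg$noise_sigma > 0) f <- f + rnorm(H * W) * noise_sd
      frames[, , fr] <- pmax(f, 0)
    }
  })
  movie_stack(frames, px, cfg$frame_rate_hz)
}

#' Simulate a movie with ground truth
#'
#' Convenience wrapper: [sample_events()] then [render_movie()].
#'
#' @inheritParams sample_events
#' @return A list with `movie` ([movie_stack()]), `truth` (event list) and
#'   `truth_table` (per-frame data frame).
#' @export
simulate_movie <- function(cfg, surface = default_surface(cfg),
                           seed = cfg$seed) {
  truth <- sample_events(cfg, surface, seed = seed)
  list(movie = render_movie(cfg, surface, truth, seed = seed),
       truth = truth, truth_table = truth_table(truth))
}

#' Score detections against ground truth
#'
#' Per-frame greedy nearest matching: candidate truth/detection pairs within
#' `match_radius_nm` are matched in order of increasing distance, each
#' entry at most once. Precision = matched / found, recall = matched /
#' truth, RMSE over matched pairs.
#'
#' @param truth_tab Data frame from [truth_table()] (columns `frame`,
#'   `x_nm`, `y_nm`).
#' @param found Localization data frame (columns `frame`, `x_nm`, `y_nm`),
#'   e.g. from [detect_stack()].
#' @param match_radius_nm Maximum truth-to-detection distance for a match.
#' @return A list with `precision`, `recall`, `rmse_nm`, `n_matched`,
#'   `n_truth`, `n_found`, and `undefined` (TRUE when a denominator was
#'   zero; precision and recall are reported as 1 when both sides are
#'   empty).
#' @export
score_detections <- function(truth_tab, found, match_radius_nm) {
  check_scalar_pos(match_radius_nm, "match_radius_nm")
  n_truth <- nrow(truth_tab); n_found <- nrow(found)
  n_matched <- 0L; sq <- numeric(0)
  if (n_truth > 0 && n_found > 0) {
    for (fr in intersect(unique(truth_tab$frame), unique(found$frame))) {
      tt <- truth_tab[truth_tab$frame == fr, , drop = FALSE]
      ff <- found[found$frame == fr, , drop = FALSE]
      d <- outer(tt$x_nm, ff$x_nm, "-")^2 + outer(tt$y_nm, ff$y_nm, "-")^2
      cand <- which(d <= match_radius_nm^2, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      ord <- order(d[cand])
      used_t <- logical(nrow(tt)); used_f <- logical(nrow(ff))
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_t[i] || used_f[j]) next
        used_t[i] <- TRUE; used_f[j] <- TRUE
        n_matched <- n_matched + 1L
        sq <- c(sq, d[cand[k, 1], cand[k, 2]])
      }
    }
  }
  undefined <- (n_truth == 0) != (n_found == 0)
  list(precision = if (n_found > 0) n_matched / n_found
                   else if (n_truth == 0) 1 else 0,
       recall = if (n_truth > 0) n_matched / n_truth
                else if (n_found == 0) 1 else 0,
       rmse_nm = if (n_matched > 0) sqrt(mean(sq)) else NA_real_,
       n_matched = n_matched, n_truth = n_truth, n_found = n_found,
       undefined = undefined)
}
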