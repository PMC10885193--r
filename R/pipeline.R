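#' Full pipeline configuration with defaults
#'
#' Builds the nested configuration consumed by [cmd_simulate()],
#' [cmd_track()] and [cmd_analyze()], merging user overrides (e.g. from
#' [read_config()]) over the defaults.
#'
#' @param overrides Named list (possibly nested) of settings to override.
#' @return Nested list with components `simulate`, `background`,
#'   `detection`, `linking`, `kinetics`, `spatial`.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    simulate = list(fov_um = 3.4, pixel_nm = 33, frame_rate_hz = 90.5,
                    n_frames = 1000, arrival_rate = 0.05,
                    mean_dwell_ms = 50, diffusion_um2_s = 0.05,
                    noise_sigma = 0.4, seed = 1,
                    blob = list(),
                    surface = list(type = "uniform")),
    background = list(window = 75, mode = "median"),
    detection = list(threshold = NULL, k_mad = 8, min_area_px = 4,
                     connectivity = 8, edge_margin_px = 1,
                     smooth_sigma_px = 2, peak_min_sep_px = 14,
                     centroid_sigma_px = 12),
    linking = list(max_disp_nm = NULL, max_gap_frames = 0),
    kinetics = list(split_threshold_ms = 110, n_boot = 10000, seed = 1,
                    min_frames = 2),
    spatial = list(bin_nm = 100))
  utils::modifyList(defaults, overrides)
}

build_surface <- function(sim, n_px) {
  s <- sim$surface
  type <- if (is.null(s$type)) "uniform" else s$type
  args <- s[setdiff(names(s), "type")]
  args <- c(list(n_px = n_px, pixel_nm = sim$pixel_nm), args)
  switch(type,
         uniform = do.call(surface_uniform, args),
         defect_square = do.call(surface_defect_square, args),
         lanes = do.call(surface_lanes, args),
         stop_invalid("unknown surface type '", type, "'"))
}

sim_config_from <- function(sim) {
  sim_config(fov_um = sim$fov_um, pixel_nm = sim$pixel_nm,
             frame_rate_hz = sim$frame_rate_hz, n_frames = sim$n_frames,
             arrival_rate = sim$arrival_rate,
             mean_dwell_ms = sim$mean_dwell_ms,
             diffusion_um2_s = sim$diffusion_um2_s,
             noise_sigma = sim$noise_sigma,
             blob = if (is.null(sim$blob)) list() else sim$blob,
             seed = sim$seed)
}

#' Simulate workflow: movie TIFF plus ground-truth CSV
#'
#' @param config Path to a YAML/JSON config file, or a (possibly partial)
#'   configuration list for [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return Invisibly, a list with the written paths (`movie`, `truth`,
#'   `manifest`) and the simulation objects.
#' @export
cmd_simulate <- function(config = list(), out_dir = ".", seed = NULL) {
  cfg_all <- if (is.character(config)) pipeline_config(read_config(config))
             else pipeline_config(config)
  if (!is.null(seed)) cfg_all$simulate$seed <- seed
  sim <- cfg_all$simulate
  cfg <- sim_config_from(sim)
  n_px <- round(cfg$fov_um * 1000 / cfg$pixel_nm)
  surface <- build_surface(sim, n_px)
  message(sprintf("[simulate] %d frames, %d x %d px, seed %d",
                  cfg$n_frames, n_px, n_px, cfg$seed))
  res <- simulate_movie(cfg, surface)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  movie_path <- file.path(out_dir, "movie.tif")
  truth_path <- file.path(out_dir, "truth.csv")
  write_movie_tiff(res$movie, movie_path)
  write_truth_csv(res$truth_table, truth_path)
  manifest <- file.path(out_dir, "simulate_manifest.json")
  write_manifest(manifest, cfg_all, cfg$seed, c(movie_path, truth_path))
  message(sprintf("[simulate] %d events, %d truth rows",
                  length(res$truth), nrow(res$truth_table)))
  invisible(list(movie = movie_path, truth = truth_path,
                 manifest = manifest, stack = res$movie,
                 truth_table = res$truth_table, surface = surface))
}

#' Track workflow: movie to localizations and trajectories
#'
#' Runs background normalisation, absolute-contrast detection and
#' trajectory linking, writing `localizations.csv`, `trajectories.csv`,
#' `trajectory_summary.csv` and `single_frame_events.csv`.
#'
#' @param movie A [movie_stack()] or path to a TIFF movie.
#' @param config Configuration list or file (see [pipeline_config()]).
#' @param out_dir Output directory.
#' @param pixel_nm,frame_rate_hz Metadata needed when `movie` is a TIFF
#'   path (defaults from the config's `simulate` block).
#' @return Invisibly, a list with `localizations`, `tracks` (a
#'   `track_set`), the detection threshold used, and the written paths.
#' @export
cmd_track <- function(movie, config = list(), out_dir = ".",
                      pixel_nm = NULL, frame_rate_hz = NULL) {
  cfg_all <- if (is.character(config)) pipeline_config(read_config(config))
             else pipeline_config(config)
  if (is.character(movie)) {
    movie <- read_movie_tiff(movie,
      pixel_nm = if (is.null(pixel_nm)) cfg_all$simulate$pixel_nm else pixel_nm,
      frame_rate_hz = if (is.null(frame_rate_hz))
        cfg_all$simulate$frame_rate_hz else frame_rate_hz)
  }
  d <- dim(movie$frames)
  message(sprintf("[track] %d frames of %d x %d px", d[3], d[1], d[2]))
  cstack <- compute_contrast(movie, window = cfg_all$background$window,
                             mode = cfg_all$background$mode)
  det <- cfg_all$detection
  thr <- if (is.null(det$threshold))
    estimate_threshold(cstack, k = det$k_mad,
                       smooth_sigma_px = det$smooth_sigma_px)
    else det$threshold
  dcfg <- detection_config(thr, det$min_area_px, det$connectivity,
                           det$edge_margin_px, det$smooth_sigma_px,
                           det$peak_min_sep_px, det$centroid_sigma_px)
  locs <- detect_stack(cstack, dcfg)
  message(sprintf("[track] threshold %.4g, %d localizations", thr, nrow(locs)))
  lnk <- cfg_all$linking
  max_disp <- if (is.null(lnk$max_disp_nm))
    default_max_disp_nm(cfg_all$simulate$diffusion_um2_s,
                        movie$frame_rate_hz, movie$pixel_nm)
    else lnk$max_disp_nm
  tracks <- link_localizations(locs, link_config(max_disp, lnk$max_gap_frames),
                               movie$frame_rate_hz)
  message(sprintf("[track] %d trajectories, %d single-frame events",
                  nrow(tracks$summary), nrow(tracks$single_frame_events)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(localizations = file.path(out_dir, "localizations.csv"),
                trajectories = file.path(out_dir, "trajectories.csv"),
                summary = file.path(out_dir, "trajectory_summary.csv"),
                single = file.path(out_dir, "single_frame_events.csv"),
                manifest = file.path(out_dir, "track_manifest.json"))
  write_table_csv(locs, paths$localizations)
  write_table_csv(tracks$trajectories, paths$trajectories)
  write_table_csv(tracks$summary, paths$summary)
  write_table_csv(tracks$single_frame_events, paths$single)
  write_manifest(paths$manifest, cfg_all, cfg_all$kinetics$seed,
                 unlist(paths[1:4]))
  invisible(list(localizations = locs, tracks = tracks, threshold = thr,
                 paths = paths))
}

#' Analyze workflow: dwell kinetics and spatial statistics
#'
#' Takes one or more named conditions, each a trajectory-summary CSV (or
#' data frame with `n_frames`/`dwell_ms`), and writes a dwell-summary JSON
#' per condition plus a rank-sum comparison JSON per condition pair. When
#' `surface` (with lane geometry) and per-condition localizations are
#' supplied, lane-relative histograms and the contrast-bias control are
#' written too.
#'
#' @param conditions Named list; each element a path to a
#'   `trajectory_summary.csv` or an equivalent data frame.
#' @param config Configuration list or file.
#' @param out_dir Output directory.
#' @param localizations Optional named list (same names) of localization
#'   CSVs/data frames for the spatial report.
#' @param surface Optional [surface_model()] with lane geometry.
#' @return Invisibly, a list with `summaries`, `comparisons`, `spatial`.
#' @export
cmd_analyze <- function(conditions, config = list(), out_dir = ".",
                        localizations = NULL, surface = NULL) {
  cfg_all <- if (is.character(config)) pipeline_config(read_config(config))
             else pipeline_config(config)
  kin <- cfg_all$kinetics
  if (length(conditions) == 0) stop_invalid("no conditions supplied")
  if (is.null(names(conditions)))
    names(conditions) <- paste0("condition", seq_along(conditions))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get_summary <- function(x) {
    df <- if (is.character(x)) read_table_csv(x, required = c("n_frames"))
          else x
    if (nrow(df) == 0) stop_invalid("empty trajectory summary")
    df
  }
  dfs <- lapply(conditions, get_summary)
  frame_rate <- cfg_all$simulate$frame_rate_hz
  summaries <- lapply(names(dfs), function(nm) {
    df <- dfs[[nm]]
    dw <- if ("dwell_ms" %in% names(df)) df$dwell_ms
          else dwell_time(df$n_frames, frame_rate)
    s <- summarize_dwells(dw, split_threshold_ms = kin$split_threshold_ms,
                          n_boot = kin$n_boot, seed = kin$seed)
    out <- list(n = s$n, mean_ms = s$mean_ms, ci_low_ms = s$ci_low_ms,
                ci_high_ms = s$ci_high_ms, exp_rate_per_ms = s$exp_rate_per_ms,
                split_threshold_ms = s$split_threshold_ms,
                split_counts = c(s$n_below_threshold, s$n_above_threshold))
    jsonlite::write_json(out, file.path(out_dir,
                                        paste0("dwell_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    s
  })
  names(summaries) <- names(dfs)
  comparisons <- list()
  nms <- names(dfs)
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      a <- dfs[[i]]; b <- dfs[[j]]
      dwa <- if ("dwell_ms" %in% names(a)) a$dwell_ms else dwell_time(a$n_frames, frame_rate)
      dwb <- if ("dwell_ms" %in% names(b)) b$dwell_ms else dwell_time(b$n_frames, frame_rate)
      cmpr <- compare_dwells(dwa, dwb)
      key <- paste0(nms[i], "_vs_", nms[j])
      comparisons[[key]] <- cmpr
      jsonlite::write_json(list(p_value = cmpr$p_value, test = cmpr$test),
                           file.path(out_dir, paste0("compare_", key, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  spatial <- NULL
  if (!is.null(localizations) && !is.null(surface)) {
    spatial <- lapply(names(localizations), function(nm) {
      locs <- localizations[[nm]]
      if (is.character(locs))
        locs <- read_table_csv(locs, required = c("x_nm", "y_nm"))
      h_cross <- lane_histogram(locs, surface, cfg_all$spatial$bin_nm, "cross")
      h_along <- lane_histogram(locs, surface, cfg_all$spatial$bin_nm, "along")
      bias <- if ("mean_abs_contrast" %in% names(locs))
        contrast_bias_check(locs, surface, cfg_all$spatial$bin_nm) else NULL
      write_table_csv(data.frame(mid_nm = h_cross$mids_nm,
                                 count = h_cross$counts),
                      file.path(out_dir, paste0("hist_cross_", nm, ".csv")))
      write_table_csv(data.frame(mid_nm = h_along$mids_nm,
                                 count = h_along$counts),
                      file.path(out_dir, paste0("hist_along_", nm, ".csv")))
      list(cross = h_cross, along = h_along,
           peak_offsets = peak_edge_offsets(h_cross), bias = bias)
    })
    names(spatial) <- names(localizations)
  }
  write_manifest(file.path(out_dir, "analyze_manifest.json"), cfg_all,
                 kin$seed)
  invisible(list(summaries = summaries, comparisons = comparisons,
                 spatial = spatial))
}
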