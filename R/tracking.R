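#' Linking configuration
#'
#' @param max_disp_nm Maximum allowed displacement per frame-to-frame link.
#' @param max_gap_frames Allowed missing frames inside a track (default 0:
#'   a molecule that vanishes for one frame ends its trajectory, and
#'   single-frame detections are counted as a separate event class).
#' @return An object of class `link_config`.
#' @export
link_config <- function(max_disp_nm, max_gap_frames = 0) {
  check_scalar_pos(max_disp_nm, "max_disp_nm")
  if (max_gap_frames < 0) stop_invalid("max_gap_frames must be >= 0")
  structure(list(max_disp_nm = max_disp_nm,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "link_config")
}

#' Default displacement gate for simulated motion
#'
#' `4 * sqrt(2 * D * dt)` (four per-axis diffusion standard deviations)
#' plus localization slack. The apparent frame-to-frame displacement of a
#' bound coil includes the localization scatter of both endpoints (about
#' 1.5 px per axis per endpoint for the default rendering), so the slack
#' default is 5 px; a gate much tighter than the apparent-step
#' distribution cuts genuine links and fragments trajectories, biasing
#' dwell times downward.
#'
#' @param diffusion_um2_s Diffusion coefficient (um^2/s).
#' @param frame_rate_hz Frame rate (Hz).
#' @param pixel_nm Pixel pitch (nm).
#' @param slack_px Localization slack in pixels (default 5).
#' @return Displacement gate in nm.
#' @export
default_max_disp_nm <- function(diffusion_um2_s, frame_rate_hz, pixel_nm,
                                slack_px = 5) {
  dt_s <- 1 / frame_rate_hz
  4 * sqrt(2 * diffusion_um2_s * dt_s) * 1000 + slack_px * pixel_nm
}

# Globally optimal one-to-one matching between two point sets subject to a
# displacement gate. Solved as a square linear assignment problem augmented
# with per-point dummy nodes priced at gate^2, so every feasible link
# (cost <= gate^2) is preferred to leaving both ends unmatched and the
# matching minimizes total squared displacement among maximal matchings.
# Returns an integer vector a with a[i] = index in (x2, y2) linked to point
# i of (x1, y1), or NA.
match_points <- function(x1, y1, x2, y2, max_disp) {
  n <- length(x1); m <- length(x2)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  gate2 <- max_disp^2
  BIG <- max(gate2, 1) * 1e8
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  d2[d2 > gate2] <- BIG
  cost <- matrix(BIG, n + m, n + m)
  cost[seq_len(n), seq_len(m)] <- d2
  cost[cbind(seq_len(n), m + seq_len(n))] <- gate2
  cost[cbind(n + seq_len(m), seq_len(m))] <- gate2
  cost[n + seq_len(m), m + seq_len(n)] <- 0
  a <- cpp_solve_lap(cost)[seq_len(n)]
  a[a > m | d2[cbind(seq_len(n), pmin(a, m))] >= BIG] <- NA_integer_
  a
}

#' Link localizations into trajectories
#'
#' Frame-to-frame linking: between each pair of consecutive occupied
#' frames, links minimize the total squared displacement over all
#' one-to-one assignments whose every link is at most `max_disp_nm`
#' (globally optimal assignment, not greedy). Unmatched detections start
#' new tracks; a track unmatched for more than `max_gap_frames` frames
#' terminates. Tracks seen in a single frame are returned separately as
#' single-frame events; trajectories require at least two frames. The
#' outputs partition the input: every localization appears exactly once.
#'
#' @param locs Localization data frame from [detect_stack()] (columns
#'   `frame`, `x_nm`, `y_nm`, plus any extras, carried through).
#' @param cfg A [link_config()].
#' @param frame_rate_hz Frame rate used to convert trajectory lengths to
#'   dwell times.
#' @return A list of class `track_set`: `trajectories` (localization rows
#'   with `trajectory_id`, >= 2 frames), `single_frame_events`
#'   (localization rows), and `summary` (per-trajectory `trajectory_id`,
#'   `n_frames`, `dwell_ms`, `start_frame`).
#' @export
link_localizations <- function(locs, cfg, frame_rate_hz) {
  check_scalar_pos(frame_rate_hz, "frame_rate_hz")
  if (nrow(locs) == 0) {
    empty <- cbind(trajectory_id = integer(0), empty_localizations())
    return(structure(list(trajectories = empty,
                          single_frame_events = empty,
                          summary = data.frame(trajectory_id = integer(0),
                                               n_frames = integer(0),
                                               dwell_ms = numeric(0),
                                               start_frame = integer(0)),
                          frame_rate_hz = frame_rate_hz),
                     class = "track_set"))
  }
  ord <- order(locs$frame, if (!is.null(locs$label)) locs$label else locs$x_nm)
  locs <- locs[ord, , drop = FALSE]
  locs$.row <- seq_len(nrow(locs))
  frames <- sort(unique(locs$frame))

  track_of_row <- integer(nrow(locs))
  next_id <- 0L
  # active tracks: data frame of id, x, y, last_frame
  act <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    last_frame = integer(0))
  for (f in frames) {
    cur <- locs[locs$frame == f, , drop = FALSE]
    live <- act[f - act$last_frame <= cfg$max_gap_frames + 1L, , drop = FALSE]
    assign_to <- rep(NA_integer_, nrow(cur))
    if (nrow(live) > 0) {
      a <- match_points(live$x, live$y, cur$x_nm, cur$y_nm, cfg$max_disp_nm)
      for (i in seq_along(a)) if (!is.na(a[i])) assign_to[a[i]] <- live$id[i]
    }
    new_idx <- which(is.na(assign_to))
    if (length(new_idx)) {
      assign_to[new_idx] <- next_id + seq_along(new_idx)
      next_id <- next_id + length(new_idx)
    }
    track_of_row[cur$.row] <- assign_to
    upd <- data.frame(id = assign_to, x = cur$x_nm, y = cur$y_nm,
                      last_frame = f)
    act <- rbind(act[!(act$id %in% assign_to), , drop = FALSE], upd)
    act <- act[f - act$last_frame <= cfg$max_gap_frames, , drop = FALSE]
  }

  locs$trajectory_id <- track_of_row
  counts <- table(track_of_row)
  multi <- as.integer(names(counts)[counts >= 2])
  is_multi <- locs$trajectory_id %in% multi
  traj <- locs[is_multi, , drop = FALSE]
  single <- locs[!is_multi, , drop = FALSE]
  traj <- traj[order(traj$trajectory_id, traj$frame), , drop = FALSE]
  # renumber trajectories consecutively by first appearance
  if (nrow(traj)) {
    traj$trajectory_id <- match(traj$trajectory_id, unique(traj$trajectory_id))
  }
  traj$.row <- NULL; single$.row <- NULL
  single$trajectory_id <- NULL
  summ <- if (nrow(traj)) {
    nloc <- as.integer(table(traj$trajectory_id))
    first <- as.integer(tapply(traj$frame, traj$trajectory_id, min))
    last <- as.integer(tapply(traj$frame, traj$trajectory_id, max))
    # with gap closing a trajectory spans its bridged frames too; dwell is
    # the total time on the surface, first to last detection inclusive
    nf <- last - first + 1L
    data.frame(trajectory_id = seq_along(nf), n_frames = nf,
               n_localizations = nloc,
               dwell_ms = dwell_time(nf, frame_rate_hz),
               start_frame = first)
  } else data.frame(trajectory_id = integer(0), n_frames = integer(0),
                    n_localizations = integer(0),
                    dwell_ms = numeric(0), start_frame = integer(0))
  structure(list(trajectories = traj, single_frame_events = single,
                 summary = summ, frame_rate_hz = frame_rate_hz),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d trajectories (>= 2 frames), %d single-frame events\n",
              nrow(x$summary), nrow(x$single_frame_events)))
  invisible(x)
}

#' Dwell time of a trajectory
#'
#' Dwell time is the total trajectory duration: number of frames times the
#' frame period.
#'
#' @param n_frames Number of frames (vectorized).
#' @param frame_rate_hz Frame rate in Hz.
#' @return Dwell time(s) in ms.
#' @examples
#' dwell_time(10, 90.5) # 110.5 ms
#' @export
dwell_time <- function(n_frames, frame_rate_hz) {
  if (any(n_frames < 1)) stop_invalid("n_frames must be >= 1")
  n_frames * frame_period_ms(frame_rate_hz)
}
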