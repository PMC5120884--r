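#' Configuration for run/turn and laser-epoch analysis
#'
#' @param turn_threshold_deg Heading change that flags a turn, degrees
#'   (default 60).
#' @param turn_window_s Window over which the heading change is measured,
#'   seconds (default 1); the difference is taken between the ends of a
#'   centered window, circularly in (-180, 180].
#' @param epoch_period_s Laser half-period, seconds (default 180: 3 min ON
#'   / 3 min OFF).
#' @param phasic_window_s Seconds of velocity averaged before and after a
#'   laser switch (default 10; use 4 for slow strains).
#' @param smooth_s Centroid box-smoothing before heading computation,
#'   seconds (default 0.5; damps pixel jitter at 30 fps).
#' @param min_step_um Displacement below which the heading is undefined and
#'   masked, um/frame.
#' @return An `opto_config` list.
#' @export
opto_config <- function(turn_threshold_deg = 60, turn_window_s = 1,
                        epoch_period_s = 180, phasic_window_s = 10,
                        smooth_s = 0.5, min_step_um = 0.1) {
  if (turn_threshold_deg <= 0 || turn_window_s <= 0)
    stopf("turn threshold and window must be positive")
  if (phasic_window_s <= 0) stopf("phasic_window_s must be positive")
  structure(
    list(turn_threshold_deg = turn_threshold_deg,
         turn_window_s = turn_window_s, epoch_period_s = epoch_period_s,
         phasic_window_s = phasic_window_s, smooth_s = smooth_s,
         min_step_um = min_step_um),
    class = "opto_config"
  )
}

#' Centroid heading of a crawling trajectory
#'
#' Box-smooths the centroid (window `cfg$smooth_s`), takes per-frame
#' displacements, and returns their direction in degrees (atan2, 0 =
#' +x, counter-clockwise). Frames whose displacement is below
#' `cfg$min_step_um` are masked (`NA`): heading is undefined when the
#' animal is effectively stationary.
#'
#' @param traj A [worm_trajectory()] with >= 2 frames.
#' @param cfg An [opto_config()].
#' @return list: `heading_deg` (per frame; last frame repeats), `step_um`
#'   (per-frame displacement of the smoothed centroid), `all_masked` flag.
#' @export
compute_heading <- function(traj, cfg = opto_config()) {
  stopifnot(inherits(traj, "worm_trajectory"))
  n <- traj$n_frames
  if (n < 2L) stopf("need at least 2 frames")
  w <- max(1L, as.integer(round(cfg$smooth_s * traj$fps)))
  cx <- box_smooth(traj$centroid[, 1], w)
  cy <- box_smooth(traj$centroid[, 2], w)
  dx <- diff(cx); dy <- diff(cy)
  step <- sqrt(dx^2 + dy^2)
  hd <- atan2(dy, dx) * 180 / pi
  hd[step < cfg$min_step_um] <- NA_real_
  hd <- c(hd, hd[n - 1L])
  step <- c(step, step[n - 1L])
  list(heading_deg = hd, step_um = step, all_masked = all(is.na(hd)))
}

#' Flag turns from a heading series
#'
#' A frame is flagged when the circular heading difference across the ends
#' of the `turn_window_s` window centered on it exceeds
#' `turn_threshold_deg` in absolute value. Contiguous flagged frames are
#' merged into single turn intervals.
#'
#' @param heading_deg Per-frame heading, degrees (`NA` = undefined).
#' @param fps Frames/s.
#' @param cfg An [opto_config()].
#' @return list: `flags` (logical per frame) and `turns` (data.frame with
#'   0-based half-open `start_frame`, `end_frame`).
#' @export
detect_turns <- function(heading_deg, fps, cfg = opto_config()) {
  n <- length(heading_deg)
  win <- as.integer(round(cfg$turn_window_s * fps))
  if (n <= win) stopf("recording shorter than the turn window")
  half_lo <- win %/% 2L
  half_hi <- win - half_lo
  flags <- rep(FALSE, n)
  i <- (half_lo + 1L):(n - half_hi)
  d <- circ_diff_deg(heading_deg[i + half_hi], heading_deg[i - half_lo])
  flags[i] <- !is.na(d) & abs(d) > cfg$turn_threshold_deg
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  turns <- data.frame(start_frame = starts[on] - 1L,
                      end_frame = ends[on])
  list(flags = flags, turns = turns)
}

#' Segment a trajectory into runs separated by turns
#'
#' Runs are the maximal turn-free intervals; each carries its duration,
#' path length (summed centroid steps), mean speed, and the laser epoch
#' (`"ON"`/`"OFF"`) containing its start frame. Runs and turns together
#' tile the recording.
#'
#' @param traj A [worm_trajectory()]; `laser_on` supplies epoch labels
#'   (all-`OFF` assumed when absent).
#' @param turn_flags Logical per-frame turn flags from [detect_turns()].
#' @param cfg An [opto_config()].
#' @return A `run_turn_segmentation`: list with `runs` (data.frame:
#'   start_frame, end_frame half-open 0-based, duration_s,
#'   path_length_um, mean_speed_um_s, epoch), `turns`, `flags`, `fps`.
#' @export
segment_runs <- function(traj, turn_flags, cfg = opto_config()) {
  stopifnot(inherits(traj, "worm_trajectory"))
  n <- traj$n_frames
  if (length(turn_flags) != n) stopf("turn_flags length must match frames")
  laser <- traj$laser_on %||% rep(FALSE, n)
  step <- row_norm2(diff(traj$centroid))
  step <- c(step, step[n - 1L])
  r <- rle(!turn_flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs_i <- which(r$values)
  runs <- do.call(rbind, lapply(runs_i, function(k) {
    idx <- starts[k]:ends[k]
    data.frame(
      start_frame = starts[k] - 1L, end_frame = ends[k],
      duration_s = length(idx) / traj$fps,
      path_length_um = sum(step[idx]),
      mean_speed_um_s = mean(step[idx]) * traj$fps,
      epoch = if (laser[starts[k]]) "ON" else "OFF",
      stringsAsFactors = FALSE)
  })) %||% data.frame(start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), path_length_um = numeric(0),
                      mean_speed_um_s = numeric(0), epoch = character(0),
                      stringsAsFactors = FALSE)
  turns <- do.call(rbind, lapply(which(!r$values), function(k)
    data.frame(start_frame = starts[k] - 1L, end_frame = ends[k]))) %||%
    data.frame(start_frame = integer(0), end_frame = integer(0))
  structure(
    list(runs = runs, turns = turns, flags = turn_flags, fps = traj$fps),
    class = "run_turn_segmentation"
  )
}

#' @export
print.run_turn_segmentation <- function(x, ...) {
  cat(sprintf("<run_turn_segmentation> %d runs, %d turns\n",
              nrow(x$runs), if (is.null(x$turns)) 0L else nrow(x$turns)))
  invisible(x)
}

#' Per-epoch run statistics
#'
#' Pools all runs starting in laser-ON vs laser-OFF epochs and reports
#' their durations, path lengths and means, with the ON/OFF mean-duration
#' ratio.
#'
#' @param seg A `run_turn_segmentation` from [segment_runs()].
#' @return list: `on`, `off` (each: n, durations, mean_duration_s,
#'   mean_path_um), `ratio_duration` (ON/OFF mean run duration;
#'   `NA` when an epoch class has no runs, with `degenerate = TRUE`).
#' @export
epoch_run_stats <- function(seg) {
  stopifnot(inherits(seg, "run_turn_segmentation"))
  one <- function(lab) {
    r <- seg$runs[seg$runs$epoch == lab, , drop = FALSE]
    list(n = nrow(r), durations = r$duration_s,
         mean_duration_s = if (nrow(r)) mean(r$duration_s) else NA_real_,
         mean_path_um = if (nrow(r)) mean(r$path_length_um) else NA_real_)
  }
  on <- one("ON"); off <- one("OFF")
  list(on = on, off = off,
       ratio_duration = on$mean_duration_s / off$mean_duration_s,
       degenerate = on$n == 0L || off$n == 0L)
}

#' Phasic velocity change around laser switch-on
#'
#' For every OFF-to-ON switch, averages the speed over the
#' `cfg$phasic_window_s` seconds before and after the switch. A switch
#' qualifies only if both windows lie inside the recording and, when `runs`
#' is supplied, inside a single run (i.e. the animal moved forward
#' continuously through the switch); other switches are excluded and
#' counted. The per-switch pre/post means are compared with a two-sided
#' Wilcoxon matched-pairs signed-rank test.
#'
#' @param speed Per-frame speed, um/s (e.g. centroid step x fps).
#' @param laser_on Logical per frame.
#' @param fps Frames/s.
#' @param cfg An [opto_config()].
#' @param runs Optional run table (from [segment_runs()]) used to require
#'   continuous forward movement across the switch.
#' @return list: `switches` (data.frame: switch_frame, pre_mean,
#'   post_mean, delta), `n_excluded`, `wilcoxon` (list statistic, p;
#'   `NULL` when fewer than 2 qualifying switches).
#' @export
phasic_velocity_change <- function(speed, laser_on, fps,
                                   cfg = opto_config(), runs = NULL) {
  n <- length(speed)
  if (length(laser_on) != n) stopf("laser_on length must match speed")
  w <- as.integer(round(cfg$phasic_window_s * fps))
  sw <- which(diff(as.integer(laser_on)) == 1L) + 1L  # first ON frame
  keep <- sw - w >= 1L & sw + w - 1L <= n
  if (!is.null(runs) && nrow(runs)) {
    inside <- vapply(sw, function(s) any(
      runs$start_frame + 1L <= s - w & runs$end_frame >= s + w - 1L),
      logical(1))
    keep <- keep & inside
  }
  n_excluded <- sum(!keep)
  sw <- sw[keep]
  if (!length(sw)) stopf("no qualifying switches")
  pre <- vapply(sw, function(s) mean(speed[(s - w):(s - 1L)]), numeric(1))
  post <- vapply(sw, function(s) mean(speed[s:(s + w - 1L)]), numeric(1))
  res <- data.frame(switch_frame = sw - 1L, pre_mean = pre,
                    post_mean = post, delta = post - pre)
  wt <- if (length(sw) >= 2L && any(res$delta != 0)) {
    h <- stats::wilcox.test(post, pre, paired = TRUE)
    list(statistic = unname(h$statistic), p = h$p.value)
  } else NULL
  list(switches = res, n_excluded = n_excluded, wilcoxon = wt)
}

#' Per-frame centroid speed
#'
#' Magnitude of the (optionally smoothed) centroid displacement times the
#' frame rate.
#'
#' @param traj A [worm_trajectory()].
#' @param smooth_s Box-smoothing window, seconds (0 = none).
#' @return Numeric vector, um/s, one per frame.
#' @export
centroid_speed <- function(traj, smooth_s = 0) {
  stopifnot(inherits(traj, "worm_trajectory"))
  n <- traj$n_frames
  w <- max(1L, as.integer(round(smooth_s * traj$fps)))
  cx <- box_smooth(traj$centroid[, 1], w)
  cy <- box_smooth(traj$centroid[, 2], w)
  sp <- sqrt(diff(cx)^2 + diff(cy)^2) * traj$fps
  c(sp, sp[n - 1L])
}
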