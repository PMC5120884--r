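#' Simulate an optogenetic run/turn session with laser epochs
#'
#' Generates a free-crawling centroid trajectory as an alternation of
#' forward runs (exponential durations, diffusing heading, state-F speed)
#' and brief sharp turns (rapid reorientation by more than 90 degrees over
#' ~0.5 s). The laser alternates OFF/ON with half-period
#' `on_off_period_s`, starting OFF. During ON epochs the mean run duration
#' is multiplied by `on_effect["run_duration"]` (applied to runs starting
#' in the epoch) and the instantaneous speed by `on_effect["speed"]`
#' (applied per frame).
#'
#' @param spec A [locomotion_sim_spec()]; `dwell_means["F"]` is the mean
#'   OFF-epoch run duration, `speeds["F"]` the baseline run speed and
#'   `heading_sd_deg` the within-run heading diffusion. Use `fps = 30` for
#'   camera-rate realism.
#' @param on_off_period_s Epoch half-period, seconds (> 0; default 180, a
#'   3-min ON / 3-min OFF cycle).
#' @param on_effect Named numeric `c(run_duration=, speed=)` multipliers,
#'   both > 0.
#' @param turn_duration_s Duration of the reorientation maneuver, seconds.
#' @param seed Integer RNG seed; overrides `spec$seed`.
#' @return list: `trajectory` (a [worm_trajectory()] with `laser_on`),
#'   `epochs` (data.frame: epoch index, label, start/end frame), and
#'   `truth` (true run intervals with their epoch at start and sampled
#'   durations, turn intervals, per-frame noiseless speed, the multipliers).
#' @export
simulate_opto_session <- function(spec, on_off_period_s = 180,
                                  on_effect = c(run_duration = 2,
                                                speed = 1.5),
                                  turn_duration_s = 0.5, seed = NULL) {
  stopifnot(inherits(spec, "locomotion_sim_spec"))
  if (on_off_period_s <= 0) stopf("on_off_period_s must be positive")
  if (any(on_effect <= 0)) stopf("on_effect multipliers must be positive")
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)

  fps <- spec$fps
  dt <- 1 / fps
  n <- as.integer(round(spec$duration_s * fps))
  t_s <- (seq_len(n) - 1L) / fps
  laser_on <- (floor(t_s / on_off_period_s) %% 2) == 1   # OFF first

  mean_run <- spec$dwell_means[["F"]]
  dur_mult <- on_effect[["run_duration"]]
  speed_mult <- on_effect[["speed"]]
  turn_frames <- max(2L, as.integer(round(turn_duration_s * fps)))

  # alternate run / turn until the recording is covered
  mode <- character(0); lens <- integer(0); run_dur <- numeric(0)
  run_epoch <- character(0)
  covered <- 0L
  while (covered < n) {
    start_on <- laser_on[covered + 1L]
    mu <- mean_run * if (start_on) dur_mult else 1
    d <- stats::rexp(1L, 1 / mu)
    len <- max(1L, as.integer(round(d * fps)))
    mode <- c(mode, "run"); lens <- c(lens, len)
    run_dur <- c(run_dur, d)
    run_epoch <- c(run_epoch, if (start_on) "ON" else "OFF")
    covered <- covered + len
    if (covered < n) {
      mode <- c(mode, "turn"); lens <- c(lens, turn_frames)
      run_dur <- c(run_dur, NA_real_); run_epoch <- c(run_epoch, NA)
      covered <- covered + turn_frames
    }
  }

  heading <- numeric(n)
  speed <- numeric(n)
  hd <- stats::runif(1, 0, 2 * pi)
  sd_step <- spec$heading_sd_deg * pi / 180 * sqrt(dt)
  pos <- 0L
  seg_rows <- list()
  for (k in seq_along(mode)) {
    len <- min(lens[k], n - pos)
    if (len <= 0L) break
    idx <- pos + seq_len(len)
    if (mode[k] == "run") {
      hd_path <- cumsum(c(hd, stats::rnorm(len - 1L, 0, sd_step)))
      sp <- pmax(stats::rnorm(len, spec$speeds[["F"]],
                              spec$speed_sd[["F"]]), 0)
    } else {
      turn_angle <- sample(c(-1, 1), 1L) *
        stats::runif(1, pi / 2, pi)            # > 90 degrees, always a turn
      hd_path <- hd + turn_angle * seq_len(len) / len
      sp <- pmax(stats::rnorm(len, spec$speeds[["F"]] / 2,
                              spec$speed_sd[["F"]]), 0)
    }
    sp <- sp * ifelse(laser_on[idx], speed_mult, 1)
    heading[idx] <- hd_path
    speed[idx] <- sp
    hd <- hd_path[len]
    seg_rows[[k]] <- data.frame(
      mode = mode[k], start_frame = pos, end_frame = pos + len,
      duration_s = len / fps, sampled_run_s = run_dur[k],
      epoch = run_epoch[k], stringsAsFactors = FALSE)
    pos <- pos + len
  }
  segments <- do.call(rbind, seg_rows)

  u <- cbind(cos(heading), sin(heading))
  step <- u * speed * dt
  centroid <- apply(step, 2, cumsum)
  centroid <- rbind(c(0, 0), centroid[-n, , drop = FALSE])
  half <- spec$body_length_um / 2
  traj <- worm_trajectory(head = centroid + half * u,
                          tail = centroid - half * u,
                          centroid = centroid, fps = fps,
                          laser_on = laser_on)

  ep_idx <- floor(t_s / on_off_period_s)
  epochs <- do.call(rbind, lapply(unique(ep_idx), function(e) {
    fr <- which(ep_idx == e)
    data.frame(epoch = e, label = if (e %% 2 == 1) "ON" else "OFF",
               start_frame = fr[1] - 1L, end_frame = fr[length(fr)],
               stringsAsFactors = FALSE)
  }))

  truth <- list(segments = segments,
                runs = segments[segments$mode == "run", , drop = FALSE],
                speed = speed, heading_deg = heading * 180 / pi,
                laser_on = laser_on, fps = fps,
                on_effect = on_effect,
                mean_run_s = mean_run)
  list(trajectory = traj, epochs = epochs, truth = truth)
}
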