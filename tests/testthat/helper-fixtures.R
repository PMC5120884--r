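# Fixture builders shared across test files.

# Straight-line trajectory: centroid advances step_um per frame along the
# heading (degrees); body axis aligned with the heading.
straight_trajectory <- function(n = 100, step_um = 10, heading_deg = 0,
                                fps = 10, body_um = 700) {
  u <- c(cos(heading_deg * pi / 180), sin(heading_deg * pi / 180))
  centroid <- cbind((0:(n - 1)) * step_um * u[1],
                    (0:(n - 1)) * step_um * u[2])
  worm_trajectory(head = centroid + body_um / 2 * rep(u, each = n),
                  tail = centroid - body_um / 2 * rep(u, each = n),
                  centroid = centroid, fps = fps)
}

rotate_xy <- function(m, theta_deg) {
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m %*% t(R)
}

rotate_trajectory <- function(traj, theta_deg) {
  worm_trajectory(head = rotate_xy(traj$head, theta_deg),
                  tail = rotate_xy(traj$tail, theta_deg),
                  centroid = rotate_xy(traj$centroid, theta_deg),
                  fps = traj$fps, laser_on = traj$laser_on)
}

# Trajectory whose centroid follows given per-frame signed speeds (um/s)
# along a fixed +x body axis.
speed_trajectory <- function(signed_speed, fps = 10, body_um = 700) {
  n <- length(signed_speed)
  x <- cumsum(c(0, signed_speed[-n] / fps))
  centroid <- cbind(x, rep(0, n))
  worm_trajectory(head = centroid + c(body_um / 2, 0),
                  tail = centroid - c(body_um / 2, 0),
                  centroid = centroid, fps = fps)
}

# Independent brute-force turn oracle: for every frame, check the circular
# heading difference across the centered window by explicit indexing.
turn_oracle <- function(heading_deg, fps, threshold = 60, window_s = 1) {
  n <- length(heading_deg)
  win <- as.integer(round(window_s * fps))
  lo <- win %/% 2L
  hi <- win - lo
  flags <- rep(FALSE, n)
  for (i in seq_len(n)) {
    a <- i - lo; b <- i + hi
    if (a < 1L || b > n) next
    d <- (heading_deg[b] - heading_deg[a]) %% 360
    if (is.na(d)) next
    if (d > 180) d <- d - 360
    flags[i] <- abs(d) > threshold
  }
  flags
}

# Brute-force BH: q_i = min over j with p_(j) >= p_i of m * p_(j) / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)            # rank of p[i]
    tail_idx <- seq(r, m)
    q[i] <- min(1, min(m * p[o[tail_idx]] / tail_idx))
  }
  q
}

# Default calcium-session study conditions: frequent, substantial
# reversals so transition analyses have events to work with.
calcium_session_spec <- function(duration_s = 900) {
  locomotion_sim_spec(duration_s = duration_s,
                      dwell_means = c(F = 15, R = 6, P = 2))
}

run_calcium_session <- function(alpha, seed, duration_s = 900) {
  loco <- calcium_session_spec(duration_s)
  s <- simulate_trajectory(loco, seed = seed)
  ca <- simulate_calcium_session(s$truth, calcium_sim_spec(alpha = alpha),
                                 seed = seed + 1L)
  v <- body_axis_velocity(s$trajectory)
  seg <- segment_states(v, loco$fps)
  ev <- detect_transitions(seg, min_from_s = 2, min_to_s = 5)
  ev <- ev[ev$type == "R->F", , drop = FALSE]
  trace <- ratiometric_dff(ca$trace$gcamp, ca$trace$rfp, loco$fps)
  list(sim = s, seg = seg, velocity = v, events = ev, trace = trace)
}
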