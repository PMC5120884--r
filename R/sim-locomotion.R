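#' Specification for the semi-Markov locomotion simulator
#'
#' Defines a three-state (forward `F`, reversal `R`, pause `P`) semi-Markov
#' crawling process: dwell times are exponential with a state-specific mean,
#' the embedded chain has no self-transitions, each state carries a mean
#' translational speed along the body axis, and the body heading diffuses by
#' Gaussian circular increments. Defaults describe a wild-type-like regime in
#' which animals spend the large majority of time (about 95\%) moving
#' forward, interrupted by brief reversals and pauses.
#'
#' @param fps Frame rate, frames/s.
#' @param duration_s Recording duration, seconds.
#' @param dwell_means Named numeric `c(F=,R=,P=)`, mean dwell time per
#'   state, seconds.
#' @param transition 3x3 row-stochastic matrix of embedded-chain transition
#'   probabilities (rows/cols ordered F, R, P); diagonal must be zero.
#' @param speeds Named numeric `c(F=,R=,P=)`, mean speed per state, um/s
#'   (pause is ~0).
#' @param speed_sd Per-state Gaussian speed noise sd, um/s. A scalar is
#'   recycled to F and R with a small pause jitter; or a named vector.
#' @param accel_tau_s Time constant with which the signed velocity
#'   approaches the state target while speeding up, seconds; crawling
#'   speed builds over a few seconds after a directional switch.
#' @param brake_tau_s Time constant while slowing down or reversing
#'   through zero, seconds (braking is much faster than acceleration).
#' @param heading_sd_deg Heading diffusion, degrees per sqrt(second).
#' @param body_length_um Head-to-tail body length, um.
#' @param seed Optional integer RNG seed stored in the spec; `simulate_*`
#'   arguments override it.
#'
#' @return A `locomotion_sim_spec` list.
#' @export
locomotion_sim_spec <- function(fps = 10,
                                duration_s = 180,
                                dwell_means = c(F = 30, R = 1.5, P = 1.5),
                                transition = NULL,
                                speeds = c(F = 150, R = 100, P = 0),
                                speed_sd = c(F = 20, R = 20, P = 4),
                                accel_tau_s = 2, brake_tau_s = 0.3,
                                heading_sd_deg = 15,
                                body_length_um = 700,
                                seed = NULL) {
  if (!is.numeric(fps) || fps <= 0) stopf("fps must be positive")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stopf("duration_s must be positive")
  states <- c("F", "R", "P")
  dwell_means <- dwell_means[states]
  if (any(is.na(dwell_means)) || any(dwell_means <= 0))
    stopf("dwell_means must be positive for F, R and P")
  speeds <- speeds[states]
  if (any(is.na(speeds)) || any(speeds < 0))
    stopf("speeds must be non-negative for F, R and P")
  if (length(speed_sd) == 1L)
    speed_sd <- c(F = speed_sd, R = speed_sd, P = min(speed_sd, 5))
  speed_sd <- speed_sd[states]
  if (any(is.na(speed_sd)) || any(speed_sd < 0))
    stopf("speed_sd must be non-negative")
  if (is.null(transition)) {
    transition <- rbind(
      F = c(0, 0.6, 0.4),
      R = c(0.85, 0, 0.15),
      P = c(0.85, 0.15, 0)
    )
    colnames(transition) <- states
  }
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(3, 3)))
    stopf("transition must be 3x3")
  dimnames(transition) <- list(states, states)
  if (any(diag(transition) != 0))
    stopf("transition diagonal (self-transitions) must be zero")
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8))
    stopf("transition rows must be non-negative and sum to 1")
  if (accel_tau_s <= 0 || brake_tau_s <= 0)
    stopf("velocity time constants must be positive")
  structure(
    list(fps = fps, duration_s = duration_s, dwell_means = dwell_means,
         transition = transition, speeds = speeds, speed_sd = speed_sd,
         accel_tau_s = accel_tau_s, brake_tau_s = brake_tau_s,
         heading_sd_deg = heading_sd_deg,
         body_length_um = body_length_um, seed = seed),
    class = "locomotion_sim_spec"
  )
}

#' Analytic stationary time fractions of a semi-Markov locomotion spec
#'
#' The long-run fraction of time in state i is
#' \eqn{\pi_i m_i / \sum_j \pi_j m_j}, where \eqn{\pi} is the stationary
#' distribution of the embedded jump chain and \eqn{m_i} the mean dwell.
#'
#' @param spec A [locomotion_sim_spec()].
#' @return Named numeric fractions for F, R, P summing to 1.
#' @export
stationary_state_fractions <- function(spec) {
  P <- spec$transition
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_embed <- Re(e$vectors[, i])
  pi_embed <- pi_embed / sum(pi_embed)
  f <- pi_embed * spec$dwell_means
  f <- f / sum(f)
  names(f) <- rownames(P)
  f
}

# Draw a semi-Markov state/dwell sequence covering at least duration_s.
draw_state_sequence <- function(spec) {
  states <- c("F", "R", "P")
  cur <- sample(states, 1L, prob = stationary_state_fractions(spec))
  seq_states <- character(0)
  seq_dwells <- numeric(0)
  total <- 0
  while (total < spec$duration_s) {
    d <- stats::rexp(1L, rate = 1 / spec$dwell_means[[cur]])
    seq_states <- c(seq_states, cur)
    seq_dwells <- c(seq_dwells, d)
    total <- total + d
    cur <- sample(states, 1L, prob = spec$transition[cur, ])
  }
  list(states = seq_states, dwells = seq_dwells)
}

#' Simulate a tracked crawling trajectory with known ground truth
#'
#' Generates per-frame head, tail and centroid coordinates (um) for a worm
#' following the semi-Markov locomotion process in `spec`. The centroid is
#' displaced along the tail-to-head unit axis by +speed in forward frames,
#' -speed in reversal frames (animals back up along the body axis, keeping
#' the same heading) and ~0 in pauses; the heading performs a Gaussian
#' circular random walk. With the same seed the output is bit-identical.
#'
#' @param spec A [locomotion_sim_spec()].
#' @param seed Integer RNG seed; overrides `spec$seed`.
#' @return A list with components `trajectory` (a [worm_trajectory()]) and
#'   `truth` — per-frame true state labels, true transition times (frame of
#'   each state change, from/to states), and the per-frame noiseless signed
#'   speed.
#' @export
simulate_trajectory <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "locomotion_sim_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)

  fps <- spec$fps
  dt <- 1 / fps
  n <- as.integer(round(spec$duration_s * fps))
  if (n < 2L) stopf("duration too short: fewer than 2 frames")

  sq <- draw_state_sequence(spec)
  bout_frames <- as.integer(pmax(1, pmin(round(sq$dwells * fps), n)))
  labels <- rep(sq$states, bout_frames)
  if (length(labels) < n) # dwell rounding undershoot: extend final state
    labels <- c(labels, rep(sq$states[length(sq$states)],
                            n - length(labels)))
  labels <- labels[seq_len(n)]

  # signed velocity follows the state target with first-order dynamics:
  # slow acceleration toward the target, fast braking when slowing down or
  # reversing through zero; starts at the first state's target (steady
  # state), so a single absorbing state yields constant speed.
  target <- ifelse(labels == "R", -1, 1) * spec$speeds[labels]
  v <- numeric(n)
  v[1] <- target[1]
  for (i in seq_len(n)[-1]) {
    tv <- target[i]
    speeding_up <- tv != 0 && v[i - 1L] * tv >= 0 &&
      abs(v[i - 1L]) < abs(tv)
    tau <- if (speeding_up) spec$accel_tau_s else spec$brake_tau_s
    v[i] <- tv + (v[i - 1L] - tv) * exp(-dt / tau)
  }
  noise_sd <- spec$speed_sd[labels]
  signed <- v + stats::rnorm(n, 0, noise_sd)

  heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n - 1, 0,
                                   spec$heading_sd_deg * pi / 180 *
                                     sqrt(dt))))
  u <- cbind(cos(heading), sin(heading))

  step <- u * signed * dt
  centroid <- apply(step, 2, cumsum)
  centroid <- rbind(c(0, 0), centroid[-n, , drop = FALSE])

  half <- spec$body_length_um / 2
  head <- centroid + half * u
  tail <- centroid - half * u

  t_s <- (seq_len(n) - 1L) / fps
  traj <- worm_trajectory(head = head, tail = tail, centroid = centroid,
                          fps = fps)

  change <- which(labels[-1] != labels[-n])
  transitions <- data.frame(
    frame = change + 1L,           # 0-based frame index of the new bout
    t_s = t_s[change + 1L],
    from = labels[change],
    to = labels[change + 1L],
    stringsAsFactors = FALSE
  )
  transitions$frame <- transitions$frame - 1L

  truth <- list(states = labels, transitions = transitions,
                signed_speed = v, fps = fps)
  list(trajectory = traj, truth = truth)
}
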