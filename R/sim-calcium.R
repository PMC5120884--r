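#' Specification for the two-channel calcium simulator
#'
#' The simulated neuron's activity `a(t)` is a first-order low-pass filter
#' (time constant `tau_s`) of the forward-state indicator delayed by
#' `lag_s`. GCaMP reports `F0 * (1 + alpha * a(t))`, RFP is
#' activity-independent at `R0`; both channels are multiplied by a shared
#' motion artifact `m(t)` (sinusoidal, amplitude `artifact_amp`) and carry
#' independent Gaussian noise. The onset lag is short (calcium indicators
#' respond within about a second) while the filter makes the signal reach
#' its plateau only after 2-3 time constants, so with the defaults (lag
#' 1 s, tau 3 s) the ratiometric signal peaks roughly 8-10 s after a
#' reversal-to-forward transition — a neuron whose activity peak
#' substantially lags the velocity rise.
#'
#' @param alpha Coupling amplitude (dimensionless); 0 = no coupling,
#'   negative = activity suppressed by forward movement.
#' @param tau_s Response time constant, seconds (> 0).
#' @param lag_s Onset lag between state and response, seconds (>= 0).
#' @param f0,r0 Baseline GCaMP and RFP intensities, a.u. (> 0).
#' @param noise_sd Per-channel additive Gaussian noise sd, a.u.
#' @param artifact_amp Amplitude of the shared multiplicative motion
#'   artifact (0 = none).
#' @param artifact_period_s Period of the artifact sinusoid, seconds.
#' @param seed Optional integer RNG seed.
#' @return A `calcium_sim_spec` list.
#' @export
calcium_sim_spec <- function(alpha = 1, tau_s = 3, lag_s = 1,
                             f0 = 100, r0 = 100, noise_sd = 2,
                             artifact_amp = 0.2, artifact_period_s = 7,
                             seed = NULL) {
  if (tau_s <= 0) stopf("tau_s must be positive")
  if (lag_s < 0) stopf("lag_s must be non-negative")
  if (f0 <= 0 || r0 <= 0) stopf("baselines f0 and r0 must be positive")
  structure(
    list(alpha = alpha, tau_s = tau_s, lag_s = lag_s, f0 = f0, r0 = r0,
         noise_sd = noise_sd, artifact_amp = artifact_amp,
         artifact_period_s = artifact_period_s, seed = seed),
    class = "calcium_sim_spec"
  )
}

# Exact per-frame exponential update of the first-order response.
lowpass_indicator <- function(ind, fps, tau_s, lag_s, a0 = 0) {
  lag_frames <- as.integer(round(lag_s * fps))
  drive <- c(rep(ind[1], lag_frames), ind)[seq_along(ind)]
  decay <- exp(-1 / (fps * tau_s))
  a <- numeric(length(ind))
  prev <- a0
  for (i in seq_along(a)) {
    prev <- drive[i] + (prev - drive[i]) * decay
    a[i] <- prev
  }
  a
}

#' Simulate a two-channel calcium session coupled to locomotor state
#'
#' Generates GCaMP and RFP intensity series for the ground-truth state
#' labels of a simulated trajectory (see [simulate_trajectory()]):
#' `a(t)` is the lagged low-pass forward indicator,
#' `GCaMP = F0 (1 + alpha a(t)) m(t) + noise`, `RFP = R0 m(t) + noise`,
#' with a shared multiplicative artifact `m(t)`. In the noiseless limit the
#' channel ratio is exactly `F0 (1 + alpha a(t)) / R0`, independent of
#' `m(t)`.
#'
#' @param truth The `truth` component returned by [simulate_trajectory()]
#'   (needs `states` and `fps`).
#' @param spec A [calcium_sim_spec()].
#' @param seed Integer RNG seed; overrides `spec$seed`.
#' @return list: `trace` (a [ratiometric_dff()]-ready list with `gcamp`,
#'   `rfp`, `fps`), `activity` (true `a(t)`), `artifact` (true `m(t)`).
#' @export
simulate_calcium_session <- function(truth, spec, seed = NULL) {
  stopifnot(inherits(spec, "calcium_sim_spec"))
  if (is.null(truth$states) || is.null(truth$fps))
    stopf("truth must carry per-frame states and fps")
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth$states)
  fps <- truth$fps
  t_s <- (seq_len(n) - 1L) / fps
  ind <- as.numeric(truth$states == "F")
  a <- lowpass_indicator(ind, fps, spec$tau_s, spec$lag_s, a0 = ind[1])
  m <- 1 + spec$artifact_amp * sin(2 * pi * t_s / spec$artifact_period_s)
  gcamp <- spec$f0 * (1 + spec$alpha * a) * m +
    stats::rnorm(n, 0, spec$noise_sd)
  rfp <- spec$r0 * m + stats::rnorm(n, 0, spec$noise_sd)
  list(trace = list(gcamp = gcamp, rfp = rfp, fps = fps),
       activity = a, artifact = m)
}
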