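test_that("dff is zero for identical constant channels and ignores common gain", {
  tr <- ratiometric_dff(rep(50, 100), rep(50, 100), fps = 10)
  expect_equal(tr$ratio, rep(1, 100))
  expect_equal(tr$dff, rep(0, 100))

  # common multiplicative artifact leaves ratio and dff untouched
  g <- 100 + 10 * sin(seq_len(200) / 7)
  r <- rep(80, 200)
  m <- 1 + 0.4 * sin(seq_len(200) / 3)
  plain <- ratiometric_dff(g, r, fps = 10)
  gained <- ratiometric_dff(g * m, r * m, fps = 10)
  expect_equal(plain$ratio, gained$ratio, tolerance = 1e-12)
  expect_equal(plain$dff, gained$dff, tolerance = 1e-12)
})

test_that("non-positive reference frames are masked, not fatal", {
  r <- rep(10, 50); r[7] <- 0
  tr <- ratiometric_dff(rep(20, 50), r, fps = 10)
  expect_true(is.na(tr$ratio[7]))
  expect_true(is.na(tr$dff[7]))
  expect_false(anyNA(tr$dff[-7]))
})

test_that("simulated dff plateau matches the generator closed form", {
  spec <- locomotion_sim_spec(duration_s = 300,
                              dwell_means = c(F = 30, R = 5, P = 2))
  s <- simulate_trajectory(spec, seed = 13)
  cs <- calcium_sim_spec(alpha = 1, tau_s = 5, noise_sd = 0.5)
  ca <- simulate_calcium_session(s$truth, cs, seed = 14)
  tr <- ratiometric_dff(ca$trace$gcamp, ca$trace$rfp, spec$fps,
                        baseline = cs$f0 / cs$r0)
  a_max <- max(ca$activity)
  expect_equal(max(tr$dff), cs$alpha * a_max, tolerance = 0.05)
})

test_that("transitions are detected at bout boundaries", {
  v <- c(rep(-80, 100), rep(100, 200))
  seg <- segment_states(v, fps = 10)
  ev <- detect_transitions(seg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "R->F")
  expect_equal(ev$anchor_frame, 100L)

  # forward-only recording: no events
  ev0 <- detect_transitions(segment_states(rep(100, 300), fps = 10))
  expect_equal(nrow(ev0), 0L)

  # both directions of transition
  v2 <- c(rep(100, 100), rep(-80, 100), rep(100, 100))
  ev2 <- detect_transitions(segment_states(v2, fps = 10))
  expect_equal(ev2$type, c("F->R", "R->F"))
})

test_that("detected anchors fall within 2 frames of true transition times", {
  spec <- calcium_session_spec(duration_s = 300)
  set.seed(31)
  errs <- unlist(lapply(1:5, function(i) {
    s <- simulate_trajectory(spec, seed = 300 + i)
    v <- body_axis_velocity(s$trajectory)
    seg <- segment_states(v, spec$fps)
    ev <- detect_transitions(seg)
    truth_rf <- s$truth$transitions
    truth_rf <- truth_rf[truth_rf$from == "R" & truth_rf$to == "F", ]
    sapply(ev$anchor_frame[ev$type == "R->F"], function(a)
      min(abs(truth_rf$frame - a)))
  }))
  expect_gte(length(errs), 10)
  expect_lte(median(errs), 2)
  expect_gte(mean(errs <= 3), 0.85)
})

test_that("velocity rate and calcium slope follow their defining formulas", {
  # trough -50 at frame 10, peak +150 at frame 20 (0-based), 10 frames apart
  v <- rep(100, 40)
  v[1:15] <- -30; v[11] <- -50                 # R bout, trough at index 11
  v[21] <- 150                                 # peak inside the F bout
  seg <- segment_states(v, fps = 10)
  ev <- detect_transitions(seg)
  dff <- rep(0, 40)
  dff[11:21] <- seq(0, 1, length.out = 11)     # linear ramp over the window
  rates <- transition_rates(ev, seg, v, dff)
  expect_equal(nrow(rates), 1L)
  expect_equal(rates$v_trough, -50)
  expect_equal(rates$v_peak, 150)
  expect_equal(rates$n_frames, 10L)
  expect_equal(rates$velocity_rate, (150 - (-50)) / 10)
  expect_equal(rates$ca_slope, 0.1, tolerance = 1e-9)
})

test_that("deceleration events use the mirrored formula and are negative", {
  v <- c(rep(150, 20), rep(-100, 20))
  v[10] <- 160; v[30] <- -120
  seg <- segment_states(v, fps = 10)
  ev <- detect_transitions(seg)
  rates <- transition_rates(ev, seg, v, rep(0, 40))
  expect_equal(rates$type, "F->R")
  expect_equal(rates$velocity_rate, (-120 - 160) / (30 - 10))
  expect_lt(rates$velocity_rate, 0)
})

test_that("event-aligned averages behave on identical and mirrored events", {
  sig <- rep(0, 400)
  bump <- dnorm(seq(-3, 3, length.out = 21))
  for (a in c(100, 200, 300)) sig[(a - 10):(a + 10)] <- bump
  events <- data.frame(anchor_frame = c(99, 199, 299))
  avg <- event_aligned_average(events, sig, fps = 10, window_s = 1)
  expect_equal(avg$n, 3L)
  expect_equal(avg$sem, rep(0, 21), tolerance = 1e-12)
  expect_equal(avg$mean, sig[90:110], tolerance = 1e-12)

  # two traces mirrored about a midline average to the midline
  s2 <- rep(1, 100); s2[40:60] <- 2
  s3 <- rep(1, 100); s3[40:60] <- 0
  ev2 <- data.frame(anchor_frame = c(49, 49))
  avg2 <- event_aligned_average(ev2, c(s2, 0)[1:100], 10, window_s = 0.5)
  m1 <- event_aligned_average(data.frame(anchor_frame = 49), s2, 10, 0.5)$mean
  m2 <- event_aligned_average(data.frame(anchor_frame = 49), s3, 10, 0.5)$mean
  both <- rbind(m1, m2)
  expect_equal(colMeans(both), rep(1, ncol(both)))
})

test_that("aligned mean rises with the expected indicator delay", {
  set.seed(55)
  loco <- calcium_session_spec(duration_s = 900)
  s <- simulate_trajectory(loco, seed = 61)
  cs <- calcium_sim_spec(noise_sd = 0.5)
  ca <- simulate_calcium_session(s$truth, cs, seed = 62)
  v <- body_axis_velocity(s$trajectory)
  seg <- segment_states(v, loco$fps)
  ev <- detect_transitions(seg, min_from_s = 2, min_to_s = 8)
  ev <- ev[ev$type == "R->F", , drop = FALSE]
  tr <- ratiometric_dff(ca$trace$gcamp, ca$trace$rfp, loco$fps)
  avg <- event_aligned_average(ev, ca$activity, loco$fps, window_s = 15)
  post <- avg$mean[avg$t_s >= 0]
  t_post <- avg$t_s[avg$t_s >= 0]
  lo <- min(avg$mean); hi <- max(post)
  half_t <- t_post[which(post >= lo + 0.5 * (hi - lo) &
                           t_post > t_post[which.min(avg$mean[avg$t_s >= -1])])][1]
  # half-rise a few seconds after the anchor: lag + tau*ln2 up to dip timing
  expect_gt(half_t, cs$lag_s)
  expect_lt(half_t, cs$lag_s + 4 * cs$tau_s)
})

test_that("rate correlation is exact for linear coupling and flags degeneracy", {
  rates <- data.frame(velocity_rate = c(1, 2, 3, 4, 5),
                      ca_slope = 2 * c(1, 2, 3, 4, 5))
  rc <- rate_correlation(rates)
  expect_equal(rc$r, 1.0, tolerance = 1e-12)

  const <- data.frame(velocity_rate = c(1, 2, 3), ca_slope = c(1, 1, 1))
  expect_true(rate_correlation(const)$degenerate)
  expect_error(rate_correlation(rates[1:2, ]), ">= 3")
})

test_that("correlation inference is calibrated on independent pairs", {
  set.seed(77)
  rej <- mean(replicate(1000, {
    d <- data.frame(velocity_rate = rnorm(12), ca_slope = rnorm(12))
    rate_correlation(d)$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("uncoupled sessions show no rate correlation bias", {
  rates <- do.call(rbind, lapply(1:5, function(i) {
    out <- run_calcium_session(alpha = 0, seed = 900 + 17 * i)
    transition_rates(out$events, out$seg, out$velocity, out$trace$dff)
  }))
  expect_gte(nrow(rates), 30)
  rc <- rate_correlation(rates)
  expect_lt(abs(rc$r), 0.35)
})
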