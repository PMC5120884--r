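#' Ratiometric calcium trace (GCaMP/RFP) with \eqn{\Delta F/F}
#'
#' The GCaMP/RFP ratio cancels motion artifacts that scale both channels by
#' the same factor; \eqn{\Delta F/F} then normalizes the ratio to a
#' baseline. The default baseline is the 10th percentile of the ratio over
#' the recording (robust to activity transients); a fixed value or the mean
#' of a reference window can be supplied instead.
#'
#' Frames where RFP is non-positive cannot define a ratio and are masked
#' (`NA`).
#'
#' @param gcamp,rfp Equal-length per-frame intensities, arbitrary units.
#' @param fps Frames/s.
#' @param baseline Either `"q10"` (default; 10th percentile of the ratio),
#'   a single numeric baseline ratio, or an integer vector of frame indices
#'   whose mean ratio is the baseline.
#' @return A `calcium_trace`: list with `gcamp`, `rfp`, `ratio`, `dff`
#'   (= (ratio - baseline)/baseline), `baseline`, `fps`.
#' @export
ratiometric_dff <- function(gcamp, rfp, fps, baseline = "q10") {
  if (length(gcamp) != length(rfp))
    stopf("gcamp and rfp must have equal length")
  ratio <- ifelse(rfp > 0, gcamp / rfp, NA_real_)
  b <- if (identical(baseline, "q10")) {
    stats::quantile(ratio, 0.10, na.rm = TRUE, names = FALSE)
  } else if (is.numeric(baseline) && length(baseline) == 1L) {
    baseline
  } else if (is.numeric(baseline)) {
    mean(ratio[baseline], na.rm = TRUE)
  } else stopf("unsupported baseline rule")
  if (!is.finite(b) || b <= 0) stopf("baseline ratio must be positive")
  structure(
    list(gcamp = gcamp, rfp = rfp, ratio = ratio,
         dff = (ratio - b) / b, baseline = b, fps = fps),
    class = "calcium_trace"
  )
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d frames @ %g fps, baseline ratio %.3f\n",
              length(x$ratio), x$fps, x$baseline))
  invisible(x)
}

#' Detect directional transitions from a bout segmentation
#'
#' One event per adjacent reversal/forward bout pair: `R->F` anchored at
#' the boundary between the two directional bouts, `F->R` symmetrically.
#' Pause bouts shorter than `max_gap_s` sitting between the two directional
#' bouts do not break adjacency; the anchor is then the midpoint of the
#' crossing gap (the instant the animal actually switched direction lies
#' inside the pause it passes through).
#'
#' Because slow calcium indicators need several seconds to respond,
#' transition analyses consider switches into sustained bouts: flanking
#' bouts shorter than `min_from_s` / `min_to_s` are skipped (both default
#' 0, i.e. keep everything; rate/slope analyses typically require a
#' sustained destination bout).
#'
#' @param seg A `state_segmentation` from [segment_states()].
#' @param max_gap_s Longest pause allowed inside a transition, seconds
#'   (default 1: a crawling worm passes through zero velocity when it
#'   reverses direction, so sub-second pauses at the boundary are part of
#'   the transition).
#' @param min_from_s,min_to_s Minimum durations of the source and
#'   destination directional bouts, seconds.
#' @return data.frame with columns `type` (`"R->F"`/`"F->R"`),
#'   `anchor_frame` (0-based), `from_bout`, `to_bout` (row indices into
#'   `seg$bouts`); zero rows when no transitions exist.
#' @export
detect_transitions <- function(seg, max_gap_s = 1,
                               min_from_s = 0, min_to_s = 0) {
  stopifnot(inherits(seg, "state_segmentation"))
  b <- seg$bouts
  out <- list()
  dir_idx <- which(b$state %in% c("F", "R"))
  for (k in seq_along(dir_idx)[-1]) {
    i <- dir_idx[k - 1L]; j <- dir_idx[k]
    if (b$state[i] == b$state[j]) next
    between <- if (j > i + 1L) seq(i + 1L, j - 1L) else integer(0)
    if (length(between) &&
        (any(b$state[between] != "P") ||
         sum(b$duration_s[between]) >= max_gap_s)) next
    if (b$duration_s[i] < min_from_s || b$duration_s[j] < min_to_s) next
    anchor <- as.integer(floor((b$end_frame[i] + b$start_frame[j]) / 2))
    out[[length(out) + 1L]] <- data.frame(
      type = paste0(b$state[i], "->", b$state[j]),
      anchor_frame = anchor,
      from_bout = i, to_bout = j, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(type = character(0), anchor_frame = integer(0),
                      from_bout = integer(0), to_bout = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Velocity rate and calcium slope across directional transitions
#'
#' For each detected event, finds the velocity trough (minimum during the
#' reversal bout) and peak (maximum during the forward bout) and computes
#' the acceleration rate for `R->F` events,
#' \eqn{(V_{peak} - V_{trough}) / \#frames}, or the deceleration rate for
#' `F->R` events, \eqn{(V_{trough} - V_{peak}) / \#frames}, where
#' `#frames` separates the trough and peak frames. The calcium rise/decay
#' is the least-squares slope of \eqn{\Delta F/F} (per frame) over the same
#' trough-to-peak interval, so that the paired quantities share a support.
#'
#' Events whose trough/peak interval is degenerate (fewer than 1 frame
#' apart) are dropped.
#'
#' @param events data.frame from [detect_transitions()].
#' @param seg The `state_segmentation` the events came from.
#' @param velocity Signed velocity, um/s.
#' @param dff \eqn{\Delta F/F} vector (same frame base), e.g.
#'   `trace$dff`.
#' @return data.frame: one row per retained event with `type`,
#'   `anchor_frame`, `trough_frame`, `peak_frame`, `v_trough`, `v_peak`,
#'   `n_frames`, `velocity_rate` (um/s per frame) and `ca_slope`
#'   (\eqn{\Delta F/F} per frame).
#' @export
transition_rates <- function(events, seg, velocity, dff) {
  stopifnot(inherits(seg, "state_segmentation"))
  b <- seg$bouts
  rows <- lapply(seq_len(nrow(events)), function(e) {
    i <- events$from_bout[e]; j <- events$to_bout[e]
    if (events$type[e] == "R->F") { rb <- i; fb <- j } else { rb <- j; fb <- i }
    r_idx <- (b$start_frame[rb] + 1L):(b$end_frame[rb])   # 1-based frames
    f_idx <- (b$start_frame[fb] + 1L):(b$end_frame[fb])
    trough <- r_idx[which.min(velocity[r_idx])]
    peak <- f_idx[which.max(velocity[f_idx])]
    nfr <- abs(peak - trough)
    if (nfr < 1L) return(NULL)
    rate <- if (events$type[e] == "R->F")
      (velocity[peak] - velocity[trough]) / nfr
    else
      (velocity[trough] - velocity[peak]) / nfr
    win <- min(trough, peak):max(trough, peak)
    y <- dff[win]
    ok <- is.finite(y)
    if (sum(ok) < 2L) return(NULL)
    slope <- stats::coef(stats::lm.fit(cbind(1, win[ok]), y[ok]))[2]
    data.frame(type = events$type[e], anchor_frame = events$anchor_frame[e],
               trough_frame = trough - 1L, peak_frame = peak - 1L,
               v_trough = velocity[trough], v_peak = velocity[peak],
               n_frames = nfr, velocity_rate = rate, ca_slope = slope,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(type = character(0), anchor_frame = integer(0),
                      trough_frame = integer(0), peak_frame = integer(0),
                      v_trough = numeric(0), v_peak = numeric(0),
                      n_frames = integer(0), velocity_rate = numeric(0),
                      ca_slope = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Event-aligned average of a signal around transition anchors
#'
#' Extracts `window_s`-second windows of `signal` centered on each event
#' anchor, keeps events fully inside the recording, and averages pointwise.
#'
#' @param events data.frame with an `anchor_frame` column (0-based).
#' @param signal Per-frame numeric vector (velocity or \eqn{\Delta F/F}).
#' @param fps Frames/s.
#' @param window_s Half-window, seconds (default 20).
#' @return list: `t_s` (time relative to anchor), `mean`, `sem`, `n`
#'   (events used), `traces` (n x length matrix).
#' @export
event_aligned_average <- function(events, signal, fps, window_s = 20) {
  half <- as.integer(round(window_s * fps))
  anchors <- events$anchor_frame + 1L            # to 1-based
  keep <- anchors - half >= 1L & anchors + half <= length(signal)
  anchors <- anchors[keep]
  if (!length(anchors)) stopf("no complete events inside the recording")
  offs <- -half:half
  traces <- t(vapply(anchors, function(a) signal[a + offs],
                     numeric(length(offs))))
  m <- colMeans(traces)
  sem <- if (nrow(traces) > 1L)
    apply(traces, 2, stats::sd) / sqrt(nrow(traces))
  else rep(0, ncol(traces))
  list(t_s = offs / fps, mean = m, sem = sem, n = nrow(traces),
       traces = traces)
}

#' Correlation between velocity rate and calcium slope
#'
#' Pearson correlation (with two-sided p value) between the per-event
#' acceleration/deceleration rate and the calcium rise/decay slope, the
#' cross-correlation analysis of transition events.
#'
#' @param rates data.frame from [transition_rates()], or any data.frame
#'   with `velocity_rate` and `ca_slope` columns.
#' @param type Optional event type filter (`"R->F"` or `"F->R"`).
#' @return list: `r`, `p`, `n`, `conf_int`, `degenerate` (TRUE when either
#'   variable has zero variance, in which case `r` is `NA`).
#' @export
rate_correlation <- function(rates, type = NULL) {
  if (!is.null(type)) rates <- rates[rates$type == type, , drop = FALSE]
  x <- rates$velocity_rate; y <- rates$ca_slope
  if (length(x) < 3L) stopf("need >= 3 events for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                conf_int = c(NA_real_, NA_real_), degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       conf_int = unname(ct$conf.int %||% c(NA_real_, NA_real_)),
       degenerate = FALSE)
}
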