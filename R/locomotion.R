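#' Segmentation configuration for bout analysis
#'
#' Encodes the minimum-bout rule (a candidate bout counts only if it lasts
#' more than `min_bout_frames` frames or at least `min_bout_s` seconds — at
#' 10 fps the two coincide at 3 frames / 300 ms), the pause speed threshold,
#' optional velocity smoothing, and how sub-minimum bouts are handled.
#'
#' @param min_bout_frames Frames; a bout must exceed this count (default 3).
#' @param min_bout_s Seconds; or reach this duration (default 0.3).
#' @param pause_threshold Speed below which a frame is a pause, um/s
#'   (default 20).
#' @param smooth_frames Box-smoothing window applied to the velocity before
#'   classification, frames (1 = none).
#' @param subminimum One of `"absorb"` (default: a sub-minimum bout flanked
#'   by a single state is relabeled to that state, otherwise to pause, then
#'   to its longer neighbour) or `"keep"` (no absorption).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(min_bout_frames = 3L, min_bout_s = 0.3,
                                pause_threshold = 20, smooth_frames = 1L,
                                subminimum = c("absorb", "keep")) {
  subminimum <- match.arg(subminimum)
  if (min_bout_frames < 1L) stopf("min_bout_frames must be >= 1")
  if (pause_threshold < 0) stopf("pause_threshold must be >= 0")
  structure(
    list(min_bout_frames = as.integer(min_bout_frames),
         min_bout_s = min_bout_s, pause_threshold = pause_threshold,
         smooth_frames = as.integer(smooth_frames),
         subminimum = subminimum),
    class = "segmentation_config"
  )
}

#' Signed body-axis velocity from a tracked trajectory
#'
#' Velocity is the per-frame centroid displacement projected on the unit
#' tail-to-head axis, times the frame rate: positive when the animal
#' advances head-first (forward), negative when it backs up. The projection
#' makes the reading invariant to rotation and translation of the field of
#' view. Frames with a degenerate body axis (head coincides with tail, e.g.
#' a tracking failure) are returned as `NA` (untracked).
#'
#' @param traj A [worm_trajectory()] with at least 2 frames.
#' @param cfg A [segmentation_config()]; only `smooth_frames` is used here.
#' @return Numeric vector, um/s, one value per frame (the last frame repeats
#'   the final forward difference); `NA` marks untracked frames.
#' @export
body_axis_velocity <- function(traj, cfg = segmentation_config()) {
  stopifnot(inherits(traj, "worm_trajectory"))
  n <- traj$n_frames
  if (n < 2L) stopf("need at least 2 frames")
  axis <- traj$head - traj$tail
  len <- row_norm2(axis)
  bad <- len < .Machine$double.eps
  u <- axis / ifelse(bad, NA_real_, len)
  disp <- diff(traj$centroid)                     # frame i -> i+1
  v <- rowSums(disp * u[-n, , drop = FALSE]) * traj$fps
  v <- c(v, v[n - 1L])                            # pad final frame
  v[bad] <- NA_real_
  if (cfg$smooth_frames > 1L) v <- box_smooth(v, cfg$smooth_frames)
  v
}

# Minimum-bout rule: frames > min_bout_frames OR duration >= min_bout_s.
bout_passes_minimum <- function(n_frames, fps, cfg) {
  (n_frames > cfg$min_bout_frames) | (n_frames / fps >= cfg$min_bout_s)
}

# Relabel sub-minimum runs until stable; one (shortest) bout per pass so
# each relabeling sees the updated neighbourhood.
absorb_subminimum <- function(labels, fps, cfg) {
  for (pass in seq_len(length(labels) + 1L)) {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k <= 1L) break
    fail <- which(!bout_passes_minimum(r$lengths, fps, cfg))
    fail <- setdiff(fail, c(1L, k))  # edge bouts are truncated, not jitter
    if (!length(fail)) break
    # handle the shortest failing bout first, then recompute runs
    i <- fail[which.min(r$lengths[fail])]
    left <- r$values[i - 1L]; right <- r$values[i + 1L]
    new_lab <- if (left == right) left
      else if (r$values[i] != "P") "P"
      else if (r$lengths[i - 1L] >= r$lengths[i + 1L]) left else right
    ends <- cumsum(r$lengths)
    idx <- (ends[i] - r$lengths[i] + 1L):ends[i]
    labels[idx] <- new_lab
  }
  labels
}

#' Segment a velocity trace into forward / reversal / pause bouts
#'
#' Frames with `|v|` at or below the pause threshold are pauses; otherwise
#' the sign of the body-axis velocity gives forward or reversal. Candidate
#' bouts failing the minimum-bout rule (more than `min_bout_frames` frames
#' or at least `min_bout_s` seconds) are absorbed so that brief tracking
#' jitter does not count as an initiation. The resulting bout table tiles
#' all tracked frames with disjoint, ordered, half-open `[start, end)`
#' intervals (0-based frames).
#'
#' @param velocity Signed velocity, um/s (`NA` = untracked), as from
#'   [body_axis_velocity()].
#' @param fps Frames/s.
#' @param cfg A [segmentation_config()].
#' @return A `state_segmentation`: list with `labels` (per-frame `"F"`,
#'   `"R"`, `"P"` or `NA` untracked), `bouts` (data.frame: state,
#'   start_frame, end_frame, n_frames, duration_s, mean_velocity,
#'   displacement_um), `fps`, and `empty` flag.
#' @export
segment_states <- function(velocity, fps, cfg = segmentation_config()) {
  n <- length(velocity)
  tracked <- !is.na(velocity)
  labels <- rep(NA_character_, n)
  if (!any(tracked)) {
    seg <- list(labels = labels,
                bouts = empty_bout_table(), fps = fps, empty = TRUE)
    class(seg) <- "state_segmentation"
    return(seg)
  }
  lab0 <- ifelse(abs(velocity) <= cfg$pause_threshold, "P",
                 ifelse(velocity > 0, "F", "R"))
  # absorb within each contiguous tracked chunk
  ch <- cumsum(c(TRUE, diff(tracked) != 0))
  for (g in unique(ch[tracked])) {
    idx <- which(ch == g & tracked)
    labels[idx] <- if (cfg$subminimum == "absorb")
      absorb_subminimum(lab0[idx], fps, cfg) else lab0[idx]
  }
  bouts <- bout_table_from_labels(labels, velocity, fps)
  seg <- list(labels = labels, bouts = bouts, fps = fps, empty = FALSE)
  class(seg) <- "state_segmentation"
  seg
}

empty_bout_table <- function() {
  data.frame(state = character(0), start_frame = integer(0),
             end_frame = integer(0), n_frames = integer(0),
             duration_s = numeric(0), mean_velocity = numeric(0),
             displacement_um = numeric(0), stringsAsFactors = FALSE)
}

bout_table_from_labels <- function(labels, velocity, fps) {
  tracked <- which(!is.na(labels))
  if (!length(tracked)) return(empty_bout_table())
  # runs within tracked chunks only
  brk <- c(TRUE, diff(tracked) != 1L |
             labels[tracked[-1]] != labels[tracked[-length(tracked)]])
  grp <- cumsum(brk)
  starts <- tracked[!duplicated(grp)]
  ends <- tracked[rev(!duplicated(rev(grp)))]
  data.frame(
    state = labels[starts],
    start_frame = starts - 1L,            # 0-based
    end_frame = ends,                     # half-open [start, end)
    n_frames = ends - starts + 1L,
    duration_s = (ends - starts + 1L) / fps,
    mean_velocity = vapply(seq_along(starts), function(i)
      mean(velocity[starts[i]:ends[i]]), numeric(1)),
    displacement_um = vapply(seq_along(starts), function(i)
      sum(velocity[starts[i]:ends[i]]) / fps, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.state_segmentation <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("F", "R", "P")))
  cat(sprintf("<state_segmentation> %d frames @ %g fps, %d bouts (F %d, R %d, P %d frames)\n",
              length(x$labels), x$fps, nrow(x$bouts),
              tab[["F"]], tab[["R"]], tab[["P"]]))
  invisible(x)
}

#' Motility metrics from a state segmentation
#'
#' Computes, per state: fraction of tracked time, initiation frequency
#' (bout starts per minute of tracked recording), mean bout duration, and
#' mean per-bout signed velocity. Untracked frames are excluded from all
#' denominators.
#'
#' @param seg A `state_segmentation` from [segment_states()].
#' @param span_s Recording span used for the initiation-frequency
#'   denominator, seconds; defaults to the tracked time in `seg`.
#' @return A `motility_metrics` list: `fractions`, `initiations_per_min`,
#'   `mean_duration_s`, `mean_velocity`, each named by state, plus
#'   `per_bout` (the bout table) and `tracked_s`.
#' @export
bout_metrics <- function(seg, span_s = NULL) {
  stopifnot(inherits(seg, "state_segmentation"))
  tracked <- sum(!is.na(seg$labels))
  if (tracked == 0L) stopf("segmentation has zero labeled frames")
  span_s <- span_s %||% (tracked / seg$fps)
  states <- c("F", "R", "P")
  nb <- seg$bouts
  frames_in <- vapply(states, function(s)
    sum(nb$n_frames[nb$state == s]), numeric(1))
  fractions <- frames_in / tracked
  inits <- vapply(states, function(s) sum(nb$state == s), numeric(1)) /
    (span_s / 60)
  mean_dur <- vapply(states, function(s) {
    d <- nb$duration_s[nb$state == s]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  mean_vel <- vapply(states, function(s) {
    v <- nb$mean_velocity[nb$state == s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  structure(
    list(fractions = fractions, initiations_per_min = inits,
         mean_duration_s = mean_dur, mean_velocity = mean_vel,
         per_bout = nb, tracked_s = tracked / seg$fps, span_s = span_s),
    class = "motility_metrics"
  )
}

#' @export
print.motility_metrics <- function(x, ...) {
  cat("<motility_metrics>\n")
  m <- rbind(fraction = x$fractions,
             `initiations/min` = x$initiations_per_min,
             `mean duration (s)` = x$mean_duration_s,
             `mean velocity (um/s)` = x$mean_velocity)
  print(round(m, 3))
  invisible(x)
}

#' Curvature kymogram from midline coordinates
#'
#' For each frame, computes the signed angle (radians) between successive
#' midline tangent vectors, anterior to posterior: a body-position x time
#' matrix whose stripes visualize propagating bending waves.
#'
#' @param traj A [worm_trajectory()] whose `midline` holds >= 3 ordered
#'   points per frame.
#' @return Numeric matrix, `(n_points - 2) x n_frames`, radians; positive =
#'   bend towards the left of the local tangent.
#' @export
curvature_kymogram <- function(traj) {
  stopifnot(inherits(traj, "worm_trajectory"))
  if (is.null(traj$midline)) stopf("trajectory has no midline")
  npts <- vapply(traj$midline, nrow, integer(1))
  if (any(npts < 3L)) stopf("need >= 3 midline points per frame")
  if (length(unique(npts)) != 1L)
    stopf("midline point count must be constant across frames")
  m <- npts[1]
  out <- vapply(traj$midline, function(pts) {
    seg <- diff(pts)                       # (m-1) tangent vectors
    a <- seg[-(m - 1L), , drop = FALSE]
    b <- seg[-1L, , drop = FALSE]
    atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
          rowSums(a * b))
  }, numeric(m - 2L))
  matrix(out, nrow = m - 2L)
}
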