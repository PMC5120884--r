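#' Tracked worm trajectory
#'
#' Container for stage-corrected planar tracking data: per-frame head, tail
#' and centroid coordinates in um at a uniform frame rate. An optional
#' midline (ordered anterior-to-posterior points per frame) supports
#' curvature kymograms; an optional `laser_on` logical marks optogenetic
#' stimulation frames.
#'
#' @param head,tail,centroid Numeric n x 2 matrices (x, y in um).
#' @param fps Frame rate, frames/s.
#' @param midline Optional list (length n) of m x 2 matrices, anterior
#'   first, or `NULL`.
#' @param laser_on Optional logical vector of length n.
#' @return A `worm_trajectory` object: list with the validated fields plus
#'   `t_s` (frame times, seconds) and `n_frames`.
#' @export
worm_trajectory <- function(head, tail, centroid, fps,
                            midline = NULL, laser_on = NULL) {
  head <- as.matrix(head); tail <- as.matrix(tail)
  centroid <- as.matrix(centroid)
  n <- nrow(head)
  if (nrow(tail) != n || nrow(centroid) != n)
    stopf("head, tail and centroid must have equal frame counts")
  if (ncol(head) != 2 || ncol(tail) != 2 || ncol(centroid) != 2)
    stopf("coordinates must be n x 2 (x, y)")
  if (!is.numeric(fps) || fps <= 0) stopf("fps must be positive")
  if (!is.null(laser_on) && length(laser_on) != n)
    stopf("laser_on must have one value per frame")
  if (!is.null(midline) && length(midline) != n)
    stopf("midline must have one point set per frame")
  structure(
    list(head = head, tail = tail, centroid = centroid, fps = fps,
         midline = midline, laser_on = laser_on,
         t_s = (seq_len(n) - 1L) / fps, n_frames = n),
    class = "worm_trajectory"
  )
}

#' @export
print.worm_trajectory <- function(x, ...) {
  cat(sprintf("<worm_trajectory> %d frames @ %g fps (%.1f s)%s%s\n",
              x$n_frames, x$fps, x$n_frames / x$fps,
              if (!is.null(x$midline)) ", with midline" else "",
              if (!is.null(x$laser_on)) ", with laser epochs" else ""))
  invisible(x)
}

#' Write / read a trajectory as columnar CSV
#'
#' Columns: `frame` (0-based), `t_s`, `head_x/y`, `tail_x/y`,
#' `centroid_x/y`, and `laser_on` when present. `fps` is recovered from the
#' `t_s` column on read.
#'
#' @param traj A [worm_trajectory()].
#' @param path Output CSV path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a [worm_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "worm_trajectory"))
  df <- data.frame(
    frame = seq_len(traj$n_frames) - 1L, t_s = traj$t_s,
    head_x = traj$head[, 1], head_y = traj$head[, 2],
    tail_x = traj$tail[, 1], tail_y = traj$tail[, 2],
    centroid_x = traj$centroid[, 1], centroid_y = traj$centroid[, 2]
  )
  if (!is.null(traj$laser_on)) df$laser_on <- as.integer(traj$laser_on)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t_s", "head_x", "head_y", "tail_x", "tail_y",
            "centroid_x", "centroid_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  fps <- 1 / stats::median(diff(df$t_s))
  worm_trajectory(
    head = cbind(df$head_x, df$head_y),
    tail = cbind(df$tail_x, df$tail_y),
    centroid = cbind(df$centroid_x, df$centroid_y),
    fps = fps,
    laser_on = if ("laser_on" %in% names(df)) df$laser_on > 0 else NULL
  )
}
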