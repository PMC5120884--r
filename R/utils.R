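# Shared small helpers (internal).

# Wrap angle differences into (-180, 180].
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Centered box smoothing with edge shrinkage; window in frames (odd forced).
box_smooth <- function(x, window) {
  if (window <= 1L) return(x)
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    k <- cn[hi + 1L] - cn[lo]
    out[i] <- if (k > 0) (cs[hi + 1L] - cs[lo]) / k else NA_real_
  }
  out
}

# Matrix row-of-2 Euclidean norms.
row_norm2 <- function(m) sqrt(rowSums(m^2))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
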