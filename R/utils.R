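# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
onh_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "onh_error")))
}

#' Linear interpolation that errors outside the covered range.
#' @noRd
interp_strict <- function(x, y, xout, what = "polyline",
                          class = "onh_coverage_error") {
  if (any(xout < x[1] - 1e-9 | xout > x[length(x)] + 1e-9)) {
    onh_stop(sprintf("%s does not cover requested positions [%g, %g]",
                     what, min(xout), max(xout)), class)
  }
  stats::approx(x, y, xout = pmin(pmax(xout, x[1]), x[length(x)]),
                method = "linear", ties = "ordered")$y
}

#' Minimum distance from point p = c(s, z) to each segment of a polyline.
#' Returns distances and the foot point coordinates, vectorised over segments.
#' @noRd
point_segment_dist <- function(p, sx, sz) {
  n <- length(sx)
  ax <- sx[-n]; az <- sz[-n]
  bx <- sx[-1]; bz <- sz[-1]
  dx <- bx - ax; dz <- bz - az
  len2 <- dx * dx + dz * dz
  t <- ((p[1] - ax) * dx + (p[2] - az) * dz) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  fx <- ax + t * dx
  fz <- az + t * dz
  d <- sqrt((p[1] - fx)^2 + (p[2] - fz)^2)
  list(dist = d, foot_s = fx, foot_z = fz)
}

#' Trapezoidal weights for possibly non-uniform, possibly gappy periodic
#' angular samples.  `theta` in degrees, strictly increasing; `valid` logical.
#' Each maximal run of valid samples is weighted trapezoidally; gaps
#' contribute nothing.  Wrap-around between last and first sample is used
#' when both are valid.
#' @noRd
angular_weights <- function(theta, valid) {
  n <- length(theta)
  w <- numeric(n)
  th <- theta
  # gap to next sample (periodic)
  gap_next <- c(diff(th), th[1] + 360 - th[n])
  gap_prev <- c(th[1] + 360 - th[n], diff(th))
  nxt <- c(seq_len(n)[-1], 1L)
  prv <- c(n, seq_len(n)[-n])
  ok <- which(valid)
  for (i in ok) {
    if (valid[nxt[i]]) w[i] <- w[i] + gap_next[i] / 2
    if (valid[prv[i]]) w[i] <- w[i] + gap_prev[i] / 2
  }
  w
}

#' Deterministic per-stream seeds derived from a master seed.
#' Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
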