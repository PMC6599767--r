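# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# row-wise Euclidean norms of an n x k matrix
row_norms <- function(m) {
  sqrt(rowSums(m * m))
}

# cross product of two 3-vectors (or row-wise for n x 3 matrices)
cross3 <- function(a, b) {
  if (is.matrix(a)) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  } else {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
}

# cycle integral of a sampled periodic signal: trapezoidal rule with the
# periodic closing sample, which on a uniform grid reduces to dt * sum(x)
cycle_integral <- function(x, dt) {
  if (length(x) == 0L) stop_invalid("empty history")
  dt * sum(x)
}

# cycle average of a sampled periodic signal
cycle_mean <- function(x) {
  if (length(x) == 0L) stop_invalid("empty history")
  mean(x)
}

check_uniform_times <- function(times, tol = 1e-9) {
  if (length(times) < 2L) stop_invalid("need at least two time samples")
  dts <- diff(times)
  if (max(abs(dts - dts[1])) > tol * max(abs(dts[1]), 1e-300)) {
    stop_invalid("time grid is not uniform")
  }
  dts[1]
}
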