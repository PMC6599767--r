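# Pulsatile WSS waveforms: truncated Fourier series for the magnitude and a
# controlled in-plane direction oscillation. These emulate the statistical
# structure of image-based haemodynamic WSS histories at the two canonical
# flow phenotypes (athero-protective: strong, near-unidirectional;
# athero-prone: weak, strongly oscillating in direction).

#' Define a pulsatile WSS waveform
#'
#' The magnitude follows a truncated Fourier series
#' `a0 + sum_k amplitudes[k] * cos(2*pi*k*(t - t_peak)/T + phases[k])` with
#' cardiac period `T`; the direction oscillates in the tangent plane with a
#' rotation angle of peak `pi * direction_osc` radians, shaped so that the
#' fraction of the cycle spent with a reversed flow-aligned component equals
#' `reversal_fraction` (possible only when `direction_osc > 0.5`).
#'
#' @param T cardiac period (s).
#' @param dt sampling time step (s); must divide `T`.
#' @param a0 mean magnitude level (Pa).
#' @param amplitudes harmonic amplitudes (Pa), harmonic 1 upward.
#' @param phases harmonic phases (rad), recycled to `length(amplitudes)`.
#' @param t_peak time shift placing the systolic peak (s).
#' @param direction_osc direction-oscillation amplitude in `[0, 1]`;
#'   0 gives a perfectly unidirectional field.
#' @param reversal_fraction target fraction of the cycle with a negative
#'   flow-aligned WSS component.
#' @param seed integer seed for the band-limited direction noise.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(T = 1.0, dt = 0.004, a0 = 1.2,
                          amplitudes = numeric(), phases = 0,
                          t_peak = 0.15, direction_osc = 0,
                          reversal_fraction = 0, seed = 1L) {
  if (T <= 0) stop_invalid("period T must be positive")
  n <- T / dt
  if (abs(n - round(n)) > 1e-12 * n) stop_invalid("dt must divide T")
  if (any(amplitudes < 0)) stop_invalid("amplitudes must be >= 0")
  if (direction_osc < 0 || direction_osc > 1) {
    stop_invalid("direction_osc must lie in [0, 1]")
  }
  if (reversal_fraction < 0 || reversal_fraction >= 1) {
    stop_invalid("reversal_fraction must lie in [0, 1)")
  }
  if (reversal_fraction > 0 && direction_osc <= 0.5) {
    stop_invalid("reversal requires direction_osc > 0.5")
  }
  if (length(amplitudes)) {
    phases <- rep_len(phases, length(amplitudes))
  } else {
    phases <- numeric()
  }
  structure(
    list(T = T, dt = dt, a0 = a0, amplitudes = as.numeric(amplitudes),
         phases = as.numeric(phases), t_peak = t_peak,
         direction_osc = direction_osc,
         reversal_fraction = reversal_fraction, seed = as.integer(seed)),
    class = "waveform_spec"
  )
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf(
    "waveform_spec: T=%g s, dt=%g s, a0=%g Pa, %d harmonics, dir osc %g, reversal %g\n",
    x$T, x$dt, x$a0, length(x$amplitudes), x$direction_osc,
    x$reversal_fraction))
  invisible(x)
}

#' Default athero-protective waveform
#'
#' High-magnitude, near-unidirectional pulsatile WSS: mean 1.2 Pa, four
#' harmonics, systolic peak about 2.5 Pa, no direction oscillation.
#'
#' @param T,dt grid parameters, see [waveform_spec()].
#' @param seed noise seed.
#' @return a `waveform_spec`.
#' @export
protective_spec <- function(T = 1.0, dt = 0.004, seed = 1L) {
  waveform_spec(T = T, dt = dt, a0 = 1.2,
                amplitudes = c(0.70, 0.35, 0.18, 0.08),
                phases = 0, t_peak = 0.15,
                direction_osc = 0, reversal_fraction = 0, seed = seed)
}

#' Default athero-prone waveform
#'
#' Low-magnitude, strongly direction-oscillating WSS: mean 0.08 Pa, peak
#' below 0.4 Pa, direction-oscillation amplitude 0.8 and a reversed
#' flow-aligned component for 30% of the cycle.
#'
#' @param T,dt grid parameters, see [waveform_spec()].
#' @param seed noise seed.
#' @return a `waveform_spec`.
#' @export
prone_spec <- function(T = 1.0, dt = 0.004, seed = 1L) {
  waveform_spec(T = T, dt = dt, a0 = 0.08,
                amplitudes = c(0.12, 0.08, 0.05),
                phases = 0, t_peak = 0.15,
                direction_osc = 0.8, reversal_fraction = 0.3, seed = seed)
}

#' Evaluate the magnitude series of a waveform
#'
#' @param t time(s) in seconds (vectorized); periodic with period `spec$T`.
#' @param spec a [waveform_spec].
#' @return WSS magnitude values (Pa); the Fourier series may dip below zero
#'   for strongly pulsatile parameter sets.
#' @export
waveform_magnitude <- function(t, spec) {
  val <- rep(spec$a0, length(t))
  if (length(spec$amplitudes)) {
    for (k in seq_along(spec$amplitudes)) {
      val <- val + spec$amplitudes[k] *
        cos(2 * pi * k * (t - spec$t_peak) / spec$T + spec$phases[k])
    }
  }
  val
}

# Rotation-angle series theta(t) realizing direction_osc and
# reversal_fraction: theta = pi*A*sign(sin)*|sin|^p, p chosen so that
# P(|theta| > pi/2) = reversal_fraction. Returns radians.
direction_angle_series <- function(t, spec) {
  A <- spec$direction_osc
  if (A == 0) return(numeric(length(t)))
  s <- sin(2 * pi * t / spec$T)
  p <- 1
  if (spec$reversal_fraction > 0) {
    # threshold on |sin|^p is c = 1/(2A); want P(|sin| > c^(1/p)) = r
    cthr <- 1 / (2 * A)
    base <- sin(pi * (1 - spec$reversal_fraction) / 2)
    p <- log(cthr) / log(base)
  }
  pi * A * sign(s) * abs(s)^p
}

# uniform one-cycle sample grid t = 0, dt, ..., T - dt
waveform_times <- function(spec) {
  n <- round(spec$T / spec$dt)
  spec$dt * (seq_len(n) - 1L)
}
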