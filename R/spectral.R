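# Frequency-domain characterization of stimulus and transmitted force.
# Spectra are computed on exactly one cycle (periodic by construction): no
# windowing, no zero padding. DFT amplitudes are normalized by the sample
# count so harmonic 0 equals the signal mean; Parseval then reads
# sum_n |X_n|^2 (two-sided) = mean(x^2).

#' Project a tangential vector history onto a local frame
#'
#' @param vector_history `n_t x 3` matrix of tangential vectors.
#' @param frame local frame from [local_frame()].
#' @return `n_t x 2` matrix of (`eta`, `zeta`) components; reconstruction
#'   `eta_comp * eta + zeta_comp * zeta` reproduces the input.
#' @export
project_to_frame <- function(vector_history, frame) {
  v <- as.matrix(vector_history)
  if (ncol(v) != 3L) stop_invalid("vector history must have 3 components")
  cbind(eta = as.numeric(v %*% frame$eta),
        zeta = as.numeric(v %*% frame$zeta))
}

#' Harmonic magnitude spectrum of a one-cycle history
#'
#' DFT of the sampled series with `X_n = fft(x)[n] / N`, reported one-sided
#' for harmonics `n = 0 .. floor(N/2)` at frequencies `n * f0`, `f0 = 1/T`.
#'
#' @param history scalar samples over exactly one cycle.
#' @param sampling_rate sampling rate (Hz); 250 Hz for the default 4 ms grid.
#' @return An object of class `spectrum_gcx`: `f0` (Hz), `harmonic`
#'   (0-based index), `freq` (Hz), `amplitude` (complex `X_n`), `magnitude`
#'   (`|X_n|`), and `power`, the total two-sided spectral power
#'   (= mean squared signal).
#' @export
magnitude_spectrum <- function(history, sampling_rate = 250) {
  x <- as.numeric(history)
  n <- length(x)
  if (n < 2L) stop_invalid("history too short")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop_invalid("sampling_rate must be positive")
  }
  X <- stats::fft(x) / n
  f0 <- sampling_rate / n
  nh <- floor(n / 2) + 1L
  structure(list(
    f0 = f0,
    harmonic = 0:(nh - 1L),
    freq = f0 * (0:(nh - 1L)),
    amplitude = X[seq_len(nh)],
    magnitude = Mod(X[seq_len(nh)]),
    power = sum(Mod(X)^2)
  ), class = "spectrum_gcx")
}

#' @export
print.spectrum_gcx <- function(x, ...) {
  cat(sprintf("spectrum: f0=%g Hz, %d harmonics, total power %g\n",
              x$f0, length(x$harmonic), x$power))
  invisible(x)
}

#' Spectral power ratio between transmitted and applied force
#'
#' Ratio of the total spectral power (all harmonics, DC included) of the
#' transmitted force-magnitude history to that of the stimulus.
#'
#' @param Fmem_mag_history,Fshear_mag_history force magnitude samples (pN)
#'   over one shared cycle grid.
#' @param sampling_rate sampling rate (Hz).
#' @return SPR (dimensionless).
#' @export
spectral_power_ratio <- function(Fmem_mag_history, Fshear_mag_history,
                                 sampling_rate = 250) {
  if (length(Fmem_mag_history) != length(Fshear_mag_history)) {
    stop_invalid("histories must share the grid")
  }
  p_mem <- magnitude_spectrum(Fmem_mag_history, sampling_rate)$power
  p_shear <- magnitude_spectrum(Fshear_mag_history, sampling_rate)$power
  if (p_shear == 0) {
    stop("SPR undefined: stimulus has zero spectral power", call. = FALSE)
  }
  p_mem / p_shear
}

#' Dominant harmonic of a spectrum
#'
#' Frequency of the maximum-magnitude harmonic among `n >= 1` (the DC term
#' is excluded, otherwise it would always dominate); ties are broken toward
#' the lowest harmonic.
#'
#' @param spectrum a `spectrum_gcx` from [magnitude_spectrum()].
#' @return dominant-harmonic frequency (Hz).
#' @export
dominant_harmonic <- function(spectrum) {
  mags <- spectrum$magnitude[-1]
  if (length(mags) < 1L) stop_invalid("need at least 2 harmonics")
  # signal-scale floor: DFT round-off of an (almost) pure-DC signal must not
  # masquerade as spectral content
  floor_ <- 1e-12 * max(spectrum$magnitude)
  if (max(mags) <= floor_) {
    stop("dominant harmonic undefined: no non-DC spectral content",
         call. = FALSE)
  }
  # ties (to relative round-off) break toward the lowest harmonic
  n_star <- which(mags >= max(mags) * (1 - 1e-9))[1]
  spectrum$f0 * n_star
}

#' Dominant harmonic ratio
#'
#' `DHR = DH(|F_mem|) / DH(|F_shear|)`; < 1 when the glycocalyx shifts the
#' dominant spectral content of the transmitted force below that of the
#' stimulus.
#'
#' @inheritParams spectral_power_ratio
#' @return DHR (dimensionless).
#' @export
dhr <- function(Fmem_mag_history, Fshear_mag_history, sampling_rate = 250) {
  dh_mem <- dominant_harmonic(magnitude_spectrum(Fmem_mag_history, sampling_rate))
  dh_shear <- dominant_harmonic(magnitude_spectrum(Fshear_mag_history, sampling_rate))
  dh_mem / dh_shear
}
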