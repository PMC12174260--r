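#' Morse-wavelet spectrogram of a spike or rate series
#'
#' Continuous wavelet transform magnitude using generalized Morse wavelets,
#' computed in the frequency domain via the FFT.  The analytic Morse
#' wavelet is `psi(omega) = U(omega) * a * omega^beta * exp(-omega^gamma)`
#' with the shape parameter `gamma = 3` and time-bandwidth product
#' `P^2 = beta * gamma = 120` (so `beta = 40`) by default, peaking at
#' `omega_p = (beta/gamma)^(1/gamma)`.  Each analysis frequency scales the
#' wavelet so its peak sits at that frequency; the filter is normalised to
#' peak value 2 (analytic convention).  Analysis frequencies span 0.5 to
#' 100 Hz on a logarithmic grid.
#'
#' @param x Numeric series (Boolean spike train or rate series).
#' @param sampling_hz Sampling frequency (Hz).
#' @param freq_min,freq_max Analysis band edges (Hz); `freq_max` is capped
#'   at the Nyquist frequency.
#' @param voices_per_octave Frequency-grid density.
#' @param gamma,time_bandwidth Morse shape and time-bandwidth parameters.
#' @return An object of class `cmc_spectrogram`: `magnitude` (frequencies
#'   by time), `freqs_hz`, `times_s`.
#' @examples
#' x <- sin(2 * pi * 40 * (0:999) / 250)
#' sp <- spectrogram(x, 250)
#' sp$freqs_hz[which.max(rowMeans(sp$magnitude))]
#' @export
spectrogram <- function(x, sampling_hz, freq_min = 0.5, freq_max = 100,
                        voices_per_octave = 12, gamma = 3,
                        time_bandwidth = 120) {
  stopifnot(sampling_hz > 0, freq_min > 0, freq_max > freq_min,
            gamma > 0, time_bandwidth > 0)
  n <- length(x)
  freq_max <- min(freq_max, sampling_hz / 2)
  if (n < 2 * sampling_hz / freq_min)
    stop("series too short for the lowest analysis frequency (need at ",
         "least two cycles)", call. = FALSE)
  beta <- time_bandwidth / gamma
  omega_p <- (beta / gamma)^(1 / gamma)

  n_oct <- log2(freq_max / freq_min)
  freqs <- freq_min * 2^(seq(0, n_oct, by = 1 / voices_per_octave))
  omega <- 2 * pi * (seq_len(n) - 1) / n      # radians per sample, [0, 2*pi)
  omega[omega >= pi] <- 0                     # analytic: zero negative band
  xf <- stats::fft(x - mean(x))

  mag <- matrix(0, length(freqs), n)
  log_peak <- beta * log(omega_p) - omega_p^gamma
  for (i in seq_along(freqs)) {
    s <- omega_p / (2 * pi * freqs[i] / sampling_hz)
    w <- s * omega
    filt <- numeric(n)
    pos <- w > 0
    filt[pos] <- 2 * exp(beta * log(w[pos]) - w[pos]^gamma - log_peak)
    mag[i, ] <- Mod(stats::fft(xf * filt, inverse = TRUE)) / n
  }
  structure(list(magnitude = mag, freqs_hz = freqs,
                 times_s = (seq_len(n) - 1) / sampling_hz),
            class = "cmc_spectrogram")
}

#' Ridge frequency and stability of a spectrogram
#'
#' The modal per-column peak frequency and the fraction of time columns
#' whose peak lies within `tol_rel` of it.  A sustained tone yields a
#' stable ridge (fraction near 1); white Bernoulli noise does not.
#'
#' @param sp A `cmc_spectrogram`.
#' @param tol_rel Relative frequency tolerance around the modal peak.
#' @return List with `ridge_hz` and `stability` in \[0, 1\].
#' @export
spectrogram_ridge <- function(sp, tol_rel = 0.15) {
  stopifnot(inherits(sp, "cmc_spectrogram"))
  peak <- sp$freqs_hz[apply(sp$magnitude, 2, which.max)]
  ridge <- stats::median(peak)
  list(ridge_hz = ridge,
       stability = mean(abs(peak - ridge) <= tol_rel * ridge))
}
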