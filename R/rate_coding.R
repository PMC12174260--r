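#' Rate-coding configuration
#'
#' Holds the sampling frequency of the simulation and the linear
#' position-to-probability encoder used for the afferents.  Neuronal
#' activity is represented as a per-sample firing probability; the
#' conversion to and from spike frequency (Hz) is
#' `probability = frequency / sampling frequency` ([freq_to_prob()]).
#'
#' The memoryless (non-temporal) engine assumes statistical independence
#' between time samples: every neuron must have returned to rest by the next
#' sample, which caps its sampling frequency at 250 Hz (a 4 ms step).  The
#' temporal-summation engine ([run_temporal_cmc()]) carries membrane state
#' across samples and may run faster (500 Hz by default).
#'
#' @param sampling_frequency_hz Samples per simulated second.  Must be
#'   positive, and at most 250 unless `temporal = TRUE`.
#' @param encoder_low,encoder_high Firing probabilities assigned to joint
#'   position 0 (full extension) and 1 (full flexion).  The proprioceptor
#'   frequency range is not biologically constrained here, so the encoder
#'   defaults to the full \[0, 1\] probability range.
#' @param temporal Logical; lifts the 250 Hz cap for the temporal engine.
#' @return An object of class `rate_coding_config`.
#' @examples
#' cfg <- rate_coding_config(250)
#' encode_position(0.5, cfg)
#' @export
rate_coding_config <- function(sampling_frequency_hz = 250,
                               encoder_low = 0, encoder_high = 1,
                               temporal = FALSE) {
  stopifnot(is.numeric(sampling_frequency_hz), length(sampling_frequency_hz) == 1)
  if (sampling_frequency_hz <= 0)
    stop("sampling_frequency_hz must be positive", call. = FALSE)
  if (!temporal && sampling_frequency_hz > 250)
    stop("the memoryless engine is capped at 250 Hz sampling; ",
         "use the temporal engine for faster sampling", call. = FALSE)
  if (!(encoder_low >= 0 && encoder_low < encoder_high && encoder_high <= 1))
    stop("need 0 <= encoder_low < encoder_high <= 1", call. = FALSE)
  structure(list(sampling_frequency_hz = sampling_frequency_hz,
                 encoder_low = encoder_low, encoder_high = encoder_high,
                 temporal = temporal),
            class = "rate_coding_config")
}

#' Convert spike frequency to per-sample firing probability
#'
#' `probability = frequency / sampling frequency`: a 50 Hz neuron sampled at
#' 100 Hz fires with probability 0.5 in each sample; at 200 Hz sampling the
#' same rate corresponds to probability 0.25.
#'
#' @param freq Spike frequency in Hz, `0 <= freq <= sampling`.
#' @param sampling Model sampling frequency in Hz, positive.
#' @return Firing probability in \[0, 1\].
#' @seealso [prob_to_freq()] for the exact inverse.
#' @export
freq_to_prob <- function(freq, sampling) {
  if (any(sampling <= 0)) stop("sampling frequency must be positive", call. = FALSE)
  if (any(freq < 0) || any(freq > sampling))
    stop("spike frequency must lie in [0, sampling frequency]", call. = FALSE)
  freq / sampling
}

#' Convert per-sample firing probability to spike frequency
#'
#' @param prob Firing probability in \[0, 1\].
#' @param sampling Model sampling frequency in Hz.
#' @return Spike frequency in Hz (`prob * sampling`).
#' @export
prob_to_freq <- function(prob, sampling) {
  if (any(sampling <= 0)) stop("sampling frequency must be positive", call. = FALSE)
  if (any(prob < 0) || any(prob > 1))
    stop("firing probability must lie in [0, 1]", call. = FALSE)
  prob * sampling
}

#' Duration of one simulation sample in milliseconds
#'
#' @param sampling Sampling frequency in Hz.
#' @return `1000 / sampling` (e.g. 4 ms at 250 Hz, 2 ms at 500 Hz).
#' @export
sampling_step_ms <- function(sampling) {
  if (any(sampling <= 0)) stop("sampling frequency must be positive", call. = FALSE)
  1000 / sampling
}

#' Sample Boolean afferent states from a firing probability
#'
#' Each afferent fires when a fresh uniform draw X satisfies
#' `X >= 1 - prob`, i.e. independently with probability exactly `prob`.
#' Draws come from the session RNG; seed with [set.seed()] for
#' reproducibility.  The endpoints are exact: `prob = 0` can never fire and
#' `prob = 1` always fires.
#'
#' @param prob Firing probability in \[0, 1\].
#' @param n Number of parallel afferents (one per micro-complex).
#' @return Integer vector of 0/1 states, length `n`.
#' @export
sample_afferent <- function(prob, n) {
  if (length(prob) != 1 || prob < 0 || prob > 1)
    stop("prob must be a single probability in [0, 1]", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  as.integer(stats::runif(n) >= 1 - prob)
}

#' Encode a joint position as an afferent firing probability
#'
#' Linear map from position (0 = full extension, 1 = full flexion) to the
#' encoder's probability range; high probability corresponds to flexion.
#' Positions outside \[0, 1\] are clamped with a warning.
#'
#' @param position Joint position, nominally in \[0, 1\].
#' @param cfg A [rate_coding_config()].
#' @return Firing probability.
#' @export
encode_position <- function(position, cfg) {
  stopifnot(inherits(cfg, "rate_coding_config"))
  if (any(position < 0) || any(position > 1)) {
    warning("position outside [0, 1] clamped", call. = FALSE)
    position <- pmin(1, pmax(0, position))
  }
  cfg$encoder_low + position * (cfg$encoder_high - cfg$encoder_low)
}
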