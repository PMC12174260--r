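# Centered moving sum and count with truncated edges (no padding; the
# divisor is the number of samples actually inside the window).
moving_window <- function(x, window) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd", call. = FALSE)
  h <- (window - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  list(sum = cs[hi + 1] - cs[lo], count = hi - lo + 1)
}

#' Centered moving mean
#'
#' Mean over a centered window of `window` samples; at the edges the window
#' is truncated to the available samples and the divisor is the count
#' actually summed.
#'
#' @param x Numeric series.
#' @param window Odd window length in samples (default 5, i.e. half-window
#'   2).
#' @return Numeric series of the same length.
#' @export
moving_mean <- function(x, window = 5) {
  w <- moving_window(x, window)
  w$sum / w$count
}

#' Intention-tremor series
#'
#' Windowed variance of the joint position around its own moving mean: for
#' each sample, the centered-window mean of the squared deviations of every
#' in-window position from that position's own moving mean.  Zero for a
#' constant series and scales quadratically with the series amplitude.
#'
#' @param x Joint-position series.
#' @param window Odd window length (default 5; half-window 2).
#' @return Non-negative tremor series of the same length.
#' @examples
#' intention_tremor(c(0, 1, 0, 1, 0))
#' @export
intention_tremor <- function(x, window = 5) {
  m <- moving_mean(x, window)
  dev2 <- (x - m)^2
  w <- moving_window(dev2, window)
  w$sum / w$count
}

#' Moving-average firing rate of a spike raster
#'
#' Boxcar mean of a Boolean spike series converted to Hz via the sampling
#' frequency ([prob_to_freq()]).
#'
#' @param raster Integer 0/1 spike series (one neuron).
#' @param sampling_hz Sampling frequency (Hz).
#' @param window Odd smoothing window in samples.
#' @return Firing-rate series in Hz.
#' @export
firing_rate_moving_average <- function(raster, sampling_hz, window = 25) {
  stopifnot(all(raster %in% c(0L, 1L)))
  prob_to_freq(moving_mean(raster, window), sampling_hz)
}

#' Afferent-grid sweep of the DCN output frequency
#'
#' Evaluates the population DCN firing probability over a grid of mossy-
#' and climbing-fibre firing probabilities, the absolute DCN-minus-climbing
#' frequency difference, and the central curve: for each climbing
#' frequency, the mossy frequency at which the DCN output matches the
#' climbing input (the argmin of the absolute difference).  The climbing
#' fibre thereby sets a central output frequency and the mossy-climbing
#' mismatch shifts the DCN output around it.
#'
#' The default `"analytic"` path uses the exact stationary marginal
#' ([dcn_marginal()]); the `"simulation"` path estimates each cell from a
#' population run (burn-in discarded) and exists to validate the analytic
#' path.
#'
#' @param cfg A [sim_config()] (homogeneous parameters).
#' @param mf_probs,cf_probs Grid axes of firing probabilities in \[0, 1\].
#' @param method `"analytic"` or `"simulation"`.
#' @param n_cmc,samples,burn_in Simulation-path population size, samples
#'   per cell and discarded initial samples.
#' @param seed Simulation-path RNG seed.
#' @return An object of class `scfh_grid`: matrices `dcn` and `abs_diff`
#'   (mossy on rows, climbing on columns; `abs_diff` in Hz), the grid axes,
#'   and `central_mf`, the per-climbing-frequency central mossy
#'   probability.
#' @examples
#' g <- scfh_sweep(sim_config(n_cmc = 1), mf_probs = seq(0, 1, 0.25),
#'                 cf_probs = seq(0, 1, 0.25))
#' g$central_mf
#' @export
scfh_sweep <- function(cfg, mf_probs = seq(0, 1, length.out = 41),
                       cf_probs = seq(0, 1, length.out = 41),
                       method = c("analytic", "simulation"),
                       n_cmc = 100000, samples = 40, burn_in = 10,
                       seed = cfg$seed) {
  stopifnot(all(mf_probs >= 0 & mf_probs <= 1),
            all(cf_probs >= 0 & cf_probs <= 1))
  method <- match.arg(method)
  nm <- length(mf_probs); nc <- length(cf_probs)
  dcn <- matrix(0, nm, nc)
  if (method == "analytic") {
    tb <- dcn_conditionals(cfg)
    for (j in seq_len(nc))
      dcn[, j] <- dcn_marginal(mf_probs, cf_probs[j], cfg, tables = tb)
  } else {
    stopifnot(samples > burn_in)
    scfg <- cfg; scfg$n_cmc <- n_cmc
    set.seed(seed)
    for (j in seq_len(nc)) for (i in seq_len(nm)) {
      r <- run_cmc_rasters(mf_probs[i], cf_probs[j], samples, scfg,
                           seed = sample.int(.Machine$integer.max, 1))
      dcn[i, j] <- mean(r$dcn[(burn_in + 1):samples, ])
    }
  }
  fs <- cfg$sampling_frequency_hz
  abs_diff <- abs(sweep(dcn, 2, cf_probs)) * fs
  central_mf <- mf_probs[apply(abs_diff, 2, which.min)]
  structure(list(mf_probs = mf_probs, cf_probs = cf_probs,
                 dcn = dcn, abs_diff = abs_diff, central_mf = central_mf,
                 method = method, sampling_hz = fs),
            class = "scfh_grid")
}

#' Long-format data frame of an afferent-grid sweep
#'
#' @param x An `scfh_grid` from [scfh_sweep()].
#' @param ... Unused.
#' @return Data frame with columns `mf_prob`, `cf_prob`, `dcn_prob`,
#'   `abs_diff_hz`.
#' @export
as.data.frame.scfh_grid <- function(x, ...) {
  data.frame(mf_prob = rep(x$mf_probs, times = length(x$cf_probs)),
             cf_prob = rep(x$cf_probs, each = length(x$mf_probs)),
             dcn_prob = as.vector(x$dcn),
             abs_diff_hz = as.vector(x$abs_diff))
}

#' Minimal circuit count for smooth movement across muscle strengths
#'
#' For each muscle strength on the ladder, searches for the smallest number
#' of parallel micro-complexes whose closed-loop sinusoid tracking keeps
#' the mean intention tremor at or below a threshold consistently (in all
#' `k` seeded replicates), by doubling from `n_start` and then bisecting.
#' The threshold defaults to the mean tremor of a reference run at
#' `reference_n` circuits (very smooth movement) times a small headroom
#' factor.
#'
#' @param cfg A [sim_config()] template; `muscle_strength` is overridden
#'   per ladder entry.
#' @param strengths Muscle-strength ladder.
#' @param desired Desired trajectory for every run.
#' @param tremor_threshold Mean-tremor threshold; `NULL` computes it from
#'   the reference run.
#' @param reference_n Circuit count of the reference run.
#' @param threshold_headroom Multiplier applied to the reference mean
#'   tremor (sampling noise allowance on the reference itself).
#' @param k Replicates that must all meet the threshold ("consistently").
#' @param n_start,n_cap Search range for the circuit count.
#' @param seed Base RNG seed; replicate seeds are derived from it.
#' @return Data frame with columns `muscle_strength`, `n_required`
#'   (`NA` when censored at `n_cap`) and `censored`.
#' @export
required_cmc_search <- function(cfg, strengths = c(2, 6, 10),
                                desired = trajectory_sinusoid(500),
                                tremor_threshold = NULL,
                                reference_n = 100000,
                                threshold_headroom = 1.5,
                                k = 3, n_start = 8, n_cap = 262144,
                                seed = cfg$seed) {
  if (is.null(tremor_threshold)) {
    ref <- cfg; ref$n_cmc <- as.integer(reference_n)
    run <- run_closed_loop(desired, ref, seed = seed)
    tremor_threshold <- mean(intention_tremor(run$actual)) * threshold_headroom
  }
  meets <- function(n, strength) {
    trial <- cfg
    trial$n_cmc <- as.integer(n)
    trial$motor$muscle_strength <- strength
    all(vapply(seq_len(k), function(r) {
      run <- run_closed_loop(desired, trial, seed = seed + 1000L * r)
      mean(intention_tremor(run$actual)) <= tremor_threshold
    }, logical(1)))
  }
  rows <- lapply(strengths, function(strength) {
    if (strength == 0)
      return(data.frame(muscle_strength = strength, n_required = n_start,
                        censored = FALSE))
    lo <- NA; hi <- NA; n <- n_start
    while (n <= n_cap) {
      if (meets(n, strength)) { hi <- n; break }
      lo <- n; n <- n * 2
    }
    if (is.na(hi))
      return(data.frame(muscle_strength = strength, n_required = NA,
                        censored = TRUE))
    if (!is.na(lo)) {
      while (hi - lo > max(1, round(lo * 0.25))) {
        mid <- floor((lo + hi) / 2)
        if (meets(mid, strength)) hi <- mid else lo <- mid
      }
    }
    data.frame(muscle_strength = strength, n_required = hi, censored = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tremor_threshold") <- tremor_threshold
  out
}

#' Polynomial fit of the circuit-requirement curve
#'
#' Least-squares polynomial (6th order by default) through the
#' strength-to-circuit-count table of [required_cmc_search()].
#'
#' @param table Result of [required_cmc_search()].
#' @param degree Polynomial degree (capped at `rows - 1`).
#' @return An `lm` fit of `n_required` on `poly(muscle_strength, degree)`.
#' @export
fit_cmc_requirement <- function(table, degree = 6) {
  tab <- table[!table$censored & !is.na(table$n_required), ]
  degree <- min(degree, nrow(tab) - 1)
  stats::lm(n_required ~ stats::poly(muscle_strength, degree), data = tab)
}
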