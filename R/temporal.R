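#' Temporal-summation configuration
#'
#' The temporal engine carries a per-neuron "neurotransmitter effect" in
#' \[-1, 1\] across samples with a linear decay, and enforces an absolute
#' refractory period: on the sample a neuron fires its effect is set to -1,
#' and the neuron cannot fire again until the effect has decayed back to 0.
#' This requires a sampling step shorter than the refractory period
#' (500 Hz sampling, i.e. a 2 ms step, against a 3 ms refractory period by
#' default); with the step equal to the refractory period the decay factor
#' is 0 and the engine reduces exactly to the memoryless model.
#'
#' @param sampling_frequency_hz Sampling frequency (Hz); the 250 Hz cap of
#'   the memoryless engine does not apply.
#' @param refractory_ms Absolute refractory period (ms).
#' @param decay Optional override of the decay factor; by default computed
#'   as `(refractory - step) / refractory` via [decay_factor()].
#' @return An object of class `temporal_config`.
#' @export
temporal_config <- function(sampling_frequency_hz = 500, refractory_ms = 3,
                            decay = NULL) {
  step <- sampling_step_ms(sampling_frequency_hz)
  if (is.null(decay)) decay <- decay_factor(refractory_ms, step)
  stopifnot(decay >= 0, decay < 1)
  structure(list(sampling_frequency_hz = sampling_frequency_hz,
                 refractory_ms = refractory_ms,
                 step_ms = step, decay = decay,
                 refractory_samples = as.integer(ceiling(refractory_ms / step) - 1)),
            class = "temporal_config")
}

#' Linear decay factor of the carried neurotransmitter effect
#'
#' `(refractory - step) / refractory`: the fraction of the carried effect
#' surviving to the next sample.  A 3 ms refractory period with a 2 ms step
#' gives 1/3; a step equal to the refractory period gives 0 (no carry-over).
#'
#' @param refractory_ms Refractory period (ms), positive.
#' @param step_ms Sampling step (ms), in `(0, refractory_ms]`.
#' @return Decay factor in \[0, 1).
#' @export
decay_factor <- function(refractory_ms, step_ms) {
  if (refractory_ms <= 0) stop("refractory period must be positive", call. = FALSE)
  if (step_ms <= 0 || step_ms > refractory_ms)
    stop("sampling step must lie in (0, refractory period]", call. = FALSE)
  (refractory_ms - step_ms) / refractory_ms
}

#' One temporal-summation update of a neuron population
#'
#' A neuron fires when the carried effect plus this sample's synaptic drive
#' strictly exceeds its DT *and* it is not inside its absolute refractory
#' window.  The stored effect becomes -1 on firing or accumulates the
#' subthreshold drive (capped to \[-1, 1\]), and in either case is
#' multiplied by the decay factor.
#'
#' The refractory lockout is an explicit countdown of
#' `ceiling(refractory/step) - 1` samples after a spike (1 sample at the
#' 3 ms / 2 ms defaults, so consecutive spikes are at least 4 ms >= 3 ms
#' apart; 0 samples when the step is at least the refractory period, the
#' memoryless limit).  The -1 imposed on the effect depresses excitability
#' over the same window; the countdown, not the sign of the decaying
#' effect, ends the lockout, because the geometric decay approaches 0
#' without reaching it.
#'
#' @param drive Signed synaptic drive this sample (vectorised per circuit).
#' @param effect Carried neurotransmitter effect in \[-1, 1\].
#' @param lock Integer vector of remaining refractory samples.
#' @param dt Depolarisation threshold (scalar or per-circuit vector).
#' @param decay Decay factor in \[0, 1).
#' @param refractory_samples Lockout length imposed on firing.
#' @return List with integer vectors `fired`, `lock` and numeric vector
#'   `effect`.
#' @export
step_temporal_neuron <- function(drive, effect, lock, dt, decay,
                                 refractory_samples) {
  stopifnot(all(effect >= -1), all(effect <= 1), all(lock >= 0))
  fired <- as.integer((effect + drive) > dt & lock == 0L)
  carried <- pmin(1, pmax(-1, effect + drive))
  new_effect <- ifelse(fired == 1L, -1, carried) * decay
  new_lock <- ifelse(fired == 1L, refractory_samples, pmax(lock - 1L, 0L))
  list(fired = fired, effect = new_effect, lock = as.integer(new_lock))
}

#' Run the temporal-summation micro-complex engine
#'
#' As [step_cmc_population()] over a series of samples, but every circuit
#' neuron passes through [step_temporal_neuron()]: synaptic drives are the
#' same independent scaled uniform draws, while subthreshold drive carries
#' over between samples and firing imposes the refractory lockout.
#' Afferent states are sampled per sample from the supplied firing
#' probabilities.  With decay factor 0 the engine consumes the identical
#' RNG stream as the memoryless model and reproduces it exactly.
#'
#' @param mf_prob,cf_prob Mossy / climbing firing probabilities: scalars or
#'   per-sample vectors of length `samples`.
#' @param samples Number of time samples.
#' @param cfg A [sim_config()] (circuit SyS/DT; `n_cmc` circuits).
#' @param tcfg A [temporal_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return List of integer matrices (`samples` rows, `n_cmc` columns) for
#'   `mossy_fibre`, `climbing_fibre`, `granule`, `golgi`, `interneuron`,
#'   `purkinje`, `dcn`, plus the configs used (class `temporal_run`).
#' @examples
#' r <- run_temporal_cmc(0.4, 0.2, samples = 50,
#'                       cfg = sim_config(n_cmc = 5), tcfg = temporal_config())
#' colMeans(r$dcn)
#' @export
run_temporal_cmc <- function(mf_prob, cf_prob, samples, cfg,
                             tcfg = temporal_config(), seed = cfg$seed) {
  validate_config(cfg)
  stopifnot(inherits(tcfg, "temporal_config"), samples >= 1)
  mf_prob <- rep_len(mf_prob, samples)
  cf_prob <- rep_len(cf_prob, samples)
  set.seed(seed)
  n <- cfg$n_cmc
  params <- cmc_params(cfg)
  decay <- tcfg$decay
  refr <- tcfg$refractory_samples
  eff <- list(granule = numeric(n), golgi = numeric(n), ii = numeric(n),
              purkinje = numeric(n), dcn = numeric(n))
  lock <- list(granule = integer(n), golgi = integer(n), ii = integer(n),
               purkinje = integer(n), dcn = integer(n))
  golgi_prev <- integer(n)
  types <- c("mossy_fibre", "climbing_fibre", "granule", "golgi",
             "interneuron", "purkinje", "dcn")
  out <- stats::setNames(lapply(types, function(.) matrix(0L, samples, n)), types)

  for (t in seq_len(samples)) {
    mossy <- sample_afferent(mf_prob[t], n)
    climbing <- sample_afferent(cf_prob[t], n)

    gr <- step_temporal_neuron(
      vnr_term(mossy, params$sys$mf_granule) -
        vnr_term(golgi_prev, params$sys$golgi_granule),
      eff$granule, lock$granule, params$dt$granule, decay, refr)
    eff$granule <- gr$effect; lock$granule <- gr$lock

    go <- step_temporal_neuron(vnr_term(gr$fired, params$sys$granule_golgi),
                               eff$golgi, lock$golgi, params$dt$golgi,
                               decay, refr)
    eff$golgi <- go$effect; lock$golgi <- go$lock

    ii <- step_temporal_neuron(vnr_term(gr$fired, params$sys$granule_ii),
                               eff$ii, lock$ii, params$dt$ii, decay, refr)
    eff$ii <- ii$effect; lock$ii <- ii$lock

    pk <- step_temporal_neuron(
      vnr_term(gr$fired, params$sys$granule_purkinje) +
        vnr_term(climbing, params$sys$cf_purkinje) -
        vnr_term(ii$fired, params$sys$ii_purkinje),
      eff$purkinje, lock$purkinje, params$dt$purkinje, decay, refr)
    eff$purkinje <- pk$effect; lock$purkinje <- pk$lock

    dc <- step_temporal_neuron(
      vnr_term(mossy, params$sys$mf_dcn) +
        vnr_term(climbing, params$sys$cf_dcn) -
        vnr_term(pk$fired, params$sys$purkinje_dcn),
      eff$dcn, lock$dcn, params$dt$dcn, decay, refr)
    eff$dcn <- dc$effect; lock$dcn <- dc$lock

    golgi_prev <- go$fired
    out$mossy_fibre[t, ] <- mossy
    out$climbing_fibre[t, ] <- climbing
    out$granule[t, ] <- gr$fired
    out$golgi[t, ] <- go$fired
    out$interneuron[t, ] <- ii$fired
    out$purkinje[t, ] <- pk$fired
    out$dcn[t, ] <- dc$fired
  }
  structure(c(out, list(cfg = cfg, tcfg = tcfg, seed = seed)),
            class = "temporal_run")
}

#' Count refractory-period violations in a raster
#'
#' Two firings of the same neuron closer than the refractory period (in
#' samples) count as one violation.  The temporal engine must produce 0.
#'
#' @param raster Integer 0/1 matrix, samples by circuits.
#' @param refractory_samples Minimum allowed spacing in samples
#'   (`ceiling(refractory_ms / step_ms)`).
#' @return Integer violation count.
#' @export
refractory_violations <- function(raster, refractory_samples) {
  stopifnot(refractory_samples >= 1)
  total <- 0L
  for (j in seq_len(ncol(raster))) {
    sp <- which(raster[, j] == 1L)
    if (length(sp) > 1)
      total <- total + sum(diff(sp) < refractory_samples)
  }
  total
}
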