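#' Comparator network between DCN output and motor signal
#'
#' Implements the cerebellar-brain-inhibition comparator: per circuit, the
#' DCN state is compared against the motor signal (the climbing-fibre state
#' for that sample) through a small Boolean network, yielding flexor and
#' extensor decisions.  The wiring, evaluated in this fixed order with
#' independent draws per term:
#'
#' * `P1`: DCN excites, motor inhibits (fires when only the DCN is active);
#' * `P2`: motor excites, DCN inhibits (fires when only the motor signal is
#'   active);
#' * `P3`: excited by both P1 and P2 (an "inputs disagree" detector);
#' * `Flexor`: P3 excites, DCN inhibits; drive multiplied by the flexor
#'   excitability gain before thresholding;
#' * `Extensor interneuron`: P3 excites, DCN inhibits;
#' * `Extensor`: P3 excites, the extensor interneuron inhibits; drive
#'   multiplied by the extensor excitability gain.
#'
#' The mutual inhibition makes simultaneous flexor and extensor firing in
#' one circuit unlikely, so each circuit casts at most one effective vote.
#'
#' @param dcn,motor_signal Integer 0/1 vectors, one element per circuit.
#' @param mparams Comparator parameters (internal `motor_params`, built
#'   from the `motor` block of [sim_config()]).
#' @return List of integer 0/1 vectors `p1`, `p2`, `p3`, `flexor`,
#'   `extensor_in`, `extensor` (class `comparator_state`).
#' @export
step_comparator <- function(dcn, motor_signal, mparams) {
  check_len(mparams$n, dcn, motor_signal)
  s <- mparams$sys; d <- mparams$dt
  p1 <- as.integer(vnr_term(dcn, s$dcn_p1) -
                     vnr_term(motor_signal, s$motor_p1) > d$p1)
  p2 <- as.integer(vnr_term(motor_signal, s$motor_p2) -
                     vnr_term(dcn, s$dcn_p2) > d$p2)
  p3 <- as.integer(vnr_term(p1, s$p1_p3) + vnr_term(p2, s$p2_p3) > d$p3)
  flexor <- as.integer((vnr_term(p3, s$p3_flexor) -
                          vnr_term(dcn, s$dcn_flexor)) *
                         mparams$flexor_excitability > d$flexor)
  ext_in <- as.integer(vnr_term(p3, s$p3_extensor_in) -
                         vnr_term(dcn, s$dcn_extensor_in) > d$extensor_in)
  extensor <- as.integer((vnr_term(p3, s$p3_extensor) -
                            vnr_term(ext_in, s$extensor_in_extensor)) *
                           mparams$extensor_excitability > d$extensor)
  structure(list(p1 = p1, p2 = p2, p3 = p3, flexor = flexor,
                 extensor_in = ext_in, extensor = extensor),
            class = "comparator_state")
}

#' Muscle power from the flexor/extensor vote
#'
#' The population vote `mean(flexor - extensor)` scaled by the muscle
#' strength (and the dimensionless `power_scale`), plus any constant
#' external force on the joint.  Power is expressed directly in
#' position-units per sample.
#'
#' @param flexor,extensor Integer 0/1 vectors.
#' @param mparams Motor parameters (carry `muscle_strength`,
#'   `power_scale`, `force_on_joint`).
#' @param force Optional override of the external force for this sample.
#' @return Scalar power.
#' @export
muscle_power <- function(flexor, extensor, mparams,
                         force = mparams$force_on_joint) {
  n <- length(flexor)
  if (n == 0) stop("muscle_power needs at least one circuit", call. = FALSE)
  if (length(extensor) != n) stop("flexor/extensor length mismatch", call. = FALSE)
  mean(flexor - extensor) * mparams$muscle_strength * mparams$power_scale + force
}

#' Diagnostic muscle power from the raw motor/DCN difference
#'
#' Simplified plant that skips the comparator network and uses
#' `mean(motor_signal - dcn)` directly.  Kept as a diagnostic; the
#' operative plant is [muscle_power()] fed by [step_comparator()].
#'
#' @inheritParams muscle_power
#' @param motor_signal,dcn Integer 0/1 vectors.
#' @export
simple_muscle_power <- function(motor_signal, dcn, mparams,
                                force = mparams$force_on_joint) {
  n <- length(motor_signal)
  if (n == 0) stop("simple_muscle_power needs at least one circuit", call. = FALSE)
  if (length(dcn) != n) stop("motor/dcn length mismatch", call. = FALSE)
  mean(motor_signal - dcn) * mparams$muscle_strength * mparams$power_scale + force
}

#' Advance the joint position by one sample
#'
#' Adds the muscle power to the position and clamps to the physical range
#' \[0, 1\] (0 full extension, 1 full flexion).
#'
#' @param position Current joint position.
#' @param power Muscle power in position-units per sample.
#' @return New position.
#' @export
update_joint <- function(position, power) {
  pmin(1, pmax(0, position + power))
}

#' Movement error
#'
#' @param actual,desired Joint positions in \[0, 1\].
#' @return `|actual - desired|`.
#' @export
movement_error <- function(actual, desired) abs(actual - desired)

#' Desired-trajectory generators
#'
#' Convenience constructors for the target joint-position series driven by
#' the closed loop: a sinusoid spanning the flexion/extension range, a
#' constant hold, and a piecewise-constant step sequence.
#'
#' @param samples Number of time samples.
#' @param sampling_hz Sampling frequency (Hz).
#' @param freq_hz Sinusoid frequency (Hz).
#' @param offset,amplitude Sinusoid midline and amplitude (positions).
#' @param phase Phase offset in radians.
#' @param value Constant position for `trajectory_constant`.
#' @param levels,lengths Step levels and their durations (samples) for
#'   `trajectory_steps`.
#' @return Numeric vector of desired positions in \[0, 1\].
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
trajectory_sinusoid <- function(samples, sampling_hz = 250, freq_hz = 0.5,
                                offset = 0.5, amplitude = 0.4, phase = 0) {
  t <- (seq_len(samples) - 1) / sampling_hz
  x <- offset + amplitude * sin(2 * pi * freq_hz * t + phase)
  if (any(x < 0) || any(x > 1))
    stop("sinusoid leaves the [0, 1] position range", call. = FALSE)
  x
}

#' @rdname trajectories
#' @export
trajectory_constant <- function(samples, value = 0.5) {
  stopifnot(value >= 0, value <= 1)
  rep(value, samples)
}

#' @rdname trajectories
#' @export
trajectory_steps <- function(levels, lengths) {
  stopifnot(length(levels) == length(lengths), all(levels >= 0),
            all(levels <= 1), all(lengths >= 1))
  rep(levels, lengths)
}

#' Closed-loop joint-position-following simulation
#'
#' Runs the full feedback loop: at each sample the actual joint position is
#' encoded as the mossy-fibre firing probability and the desired position
#' as the climbing-fibre probability; Boolean afferents are sampled for
#' every circuit; the micro-complex population is stepped
#' ([step_cmc_population()]); the DCN output and the climbing-fibre state
#' (the motor signal) feed the comparator ([step_comparator()]); the
#' flexor/extensor vote moves the joint ([muscle_power()],
#' [update_joint()]); the movement error is recorded.  When the
#' configuration carries a plasticity block, synaptic strengths are updated
#' per circuit each sample.
#'
#' @param desired Desired-position series in \[0, 1\] (see
#'   [trajectory_sinusoid()]).
#' @param cfg A [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`); the seed and config fully
#'   determine the run.
#' @param force External force on the joint: scalar or per-sample vector,
#'   overriding `cfg$motor$force_on_joint` (used for force-step
#'   experiments).
#' @param record_rates If `TRUE`, also record per-sample population mean
#'   firing probabilities of every neuron type and, when plasticity is on,
#'   the population mean of each plastic synaptic strength.
#' @return A data frame with one row per sample: `t` (sample index),
#'   `time_s`, `desired`, `actual`, `muscle_power`, `error`, plus the
#'   optional rate/SyS columns.
#' @examples
#' cfg <- sim_config(n_cmc = 200, seed = 7)
#' run <- run_closed_loop(trajectory_constant(50), cfg)
#' mean(run$error)
#' @export
run_closed_loop <- function(desired, cfg, seed = cfg$seed, force = NULL,
                            record_rates = FALSE) {
  validate_config(cfg)
  stopifnot(all(desired >= 0), all(desired <= 1), length(desired) >= 1)
  nT <- length(desired)
  if (is.null(force)) force <- cfg$motor$force_on_joint
  force <- rep_len(force, nT)
  set.seed(seed)
  n <- cfg$n_cmc
  params <- cmc_params(cfg)
  mpar <- motor_params(cfg)
  enc <- rate_coding_config(cfg$sampling_frequency_hz,
                            cfg$encoder_low, cfg$encoder_high)
  state <- cmc_state(n)
  plast <- if (!is.null(cfg$plasticity)) plasticity_state(params, cfg$plasticity)

  pos <- desired[1]
  actual <- power <- err <- numeric(nT)
  if (record_rates) {
    rates <- matrix(0, nT, 7,
                    dimnames = list(NULL, c("mossy", "climbing", "granule",
                                            "golgi", "interneuron", "purkinje",
                                            "dcn")))
    if (!is.null(plast))
      sys_trace <- matrix(0, nT, length(.plastic_synapses),
                          dimnames = list(NULL, .plastic_synapses))
  }

  for (t in seq_len(nT)) {
    mossy <- sample_afferent(encode_position(pos, enc), n)
    climbing <- sample_afferent(encode_position(desired[t], enc), n)
    state <- step_cmc_population(mossy, climbing, state, params)
    if (!is.null(plast)) {
      upd <- plasticity_step(plast, params, state, cfg$plasticity)
      plast <- upd$state; params <- upd$params
    }
    comp <- step_comparator(state$dcn, climbing, mpar)
    pw <- muscle_power(comp$flexor, comp$extensor, mpar, force = force[t])
    actual[t] <- pos
    power[t] <- pw
    err[t] <- movement_error(pos, desired[t])
    if (record_rates) {
      rates[t, ] <- c(mean(mossy), mean(climbing), mean(state$granule),
                      mean(state$golgi), mean(state$interneuron),
                      mean(state$purkinje), mean(state$dcn))
      if (!is.null(plast))
        sys_trace[t, ] <- vapply(.plastic_synapses,
                                 function(s) mean(params$sys[[s]]), numeric(1))
    }
    pos <- update_joint(pos, pw)
  }

  out <- data.frame(t = seq_len(nT),
                    time_s = (seq_len(nT) - 1) / cfg$sampling_frequency_hz,
                    desired = desired, actual = actual,
                    muscle_power = power, error = err)
  if (record_rates) {
    out <- cbind(out, as.data.frame(rates))
    if (!is.null(plast))
      out <- cbind(out, stats::setNames(as.data.frame(sys_trace),
                                        paste0("sys_", .plastic_synapses)))
  }
  out
}
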