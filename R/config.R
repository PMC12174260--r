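# Circuit synapse and neuron name sets used throughout the package.
# Synapse names are pre_post; comparator synapses live under motor$sys.
.cmc_synapses <- c("mf_granule", "golgi_granule", "granule_golgi",
                   "granule_ii", "granule_purkinje", "cf_purkinje",
                   "ii_purkinje", "mf_dcn", "cf_dcn", "purkinje_dcn")
.cmc_neurons  <- c("granule", "golgi", "ii", "purkinje", "dcn")
.motor_synapses <- c("dcn_p1", "motor_p1", "motor_p2", "dcn_p2",
                     "p1_p3", "p2_p3", "p3_flexor", "dcn_flexor",
                     "p3_extensor_in", "dcn_extensor_in",
                     "p3_extensor", "extensor_in_extensor")
.motor_neurons  <- c("p1", "p2", "p3", "flexor", "extensor_in", "extensor")

# GABAergic presynaptic cells: Golgi, inhibitory interneuron, Purkinje.
# Everything afferent- or granule-derived is glutamatergic.
.gabaergic_synapses     <- c("golgi_granule", "ii_purkinje", "purkinje_dcn")
.glutamatergic_synapses <- setdiff(.cmc_synapses, .gabaergic_synapses)

# Synapse set with presynaptic CaV2.1 dependence: granule-cell efferents,
# climbing-fibre efferents and the Purkinje terminal on the DCN.
.cacna1a_synapses <- c("granule_golgi", "granule_ii", "granule_purkinje",
                       "cf_purkinje", "cf_dcn", "purkinje_dcn")

#' Simulation configuration
#'
#' Bundles every tunable of a micro-complex simulation run: the number of
#' parallel circuits, the sampling frequency and position encoder, scalar
#' synaptic strengths (SyS) and depolarisation thresholds (DT) for the
#' circuit and for the comparator plant, the motor parameters, and an
#' optional plasticity block.  Scalars here are expanded to per-circuit
#' vectors by [cmc_params()] at run time (plasticity makes them diverge
#' across circuits).
#'
#' Defaults follow the reference operating point of the model: SyS 1.5 and
#' DT 0.15 everywhere, 100,000 parallel circuits, 250 Hz sampling, muscle
#' strength 10 and no external force.
#'
#' @param n_cmc Number of parallel micro-complexes.
#' @param sampling_frequency_hz Sampling frequency (Hz), capped at 250 for
#'   the memoryless engine.
#' @param encoder_low,encoder_high Position encoder range (see
#'   [rate_coding_config()]).
#' @param seed Default RNG seed for runs started from this configuration.
#' @param sys,dt Named lists of scalar overrides for circuit synapse
#'   strengths / neuron thresholds.  Unknown names are an error.
#' @param sys_default,dt_default Fill-in values for parameters not
#'   overridden.
#' @param motor Named list of overrides for the motor plant block
#'   (`muscle_strength`, `force_on_joint`, `flexor_excitability`,
#'   `extensor_excitability`, `power_scale`, and nested `sys` / `dt` lists
#'   for the comparator network).
#' @param plasticity `NULL` (plasticity off) or a [plasticity_config()].
#' @return An object of class `cmc_config`.
#' @examples
#' cfg <- sim_config(n_cmc = 1000, sys = list(cf_purkinje = 2))
#' cfg$sys$cf_purkinje
#' @export
sim_config <- function(n_cmc = 100000, sampling_frequency_hz = 250,
                       encoder_low = 0, encoder_high = 1, seed = 1L,
                       sys = list(), dt = list(),
                       sys_default = 1.5, dt_default = 0.15,
                       motor = list(), plasticity = NULL) {
  full_sys <- stats::setNames(as.list(rep(sys_default, length(.cmc_synapses))),
                              .cmc_synapses)
  full_dt  <- stats::setNames(as.list(rep(dt_default, length(.cmc_neurons))),
                              .cmc_neurons)
  full_sys[names(sys)] <- check_named(sys, .cmc_synapses, "sys")
  full_dt[names(dt)]   <- check_named(dt, .cmc_neurons, "dt")

  m <- list(muscle_strength = 10, force_on_joint = 0,
            flexor_excitability = 1, extensor_excitability = 1,
            power_scale = 1,
            sys = stats::setNames(as.list(rep(sys_default, length(.motor_synapses))),
                                  .motor_synapses),
            dt = stats::setNames(as.list(rep(dt_default, length(.motor_neurons))),
                                 .motor_neurons))
  if (length(motor)) {
    plain <- setdiff(names(motor), c("sys", "dt"))
    bad <- setdiff(plain, names(m))
    if (length(bad)) stop("unknown motor fields: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    m[plain] <- motor[plain]
    if (!is.null(motor$sys))
      m$sys[names(motor$sys)] <- check_named(motor$sys, .motor_synapses, "motor$sys")
    if (!is.null(motor$dt))
      m$dt[names(motor$dt)]   <- check_named(motor$dt, .motor_neurons, "motor$dt")
  }

  if (is.numeric(n_cmc) && length(n_cmc) == 1 && !is.na(n_cmc) &&
      n_cmc == round(n_cmc))
    n_cmc <- as.integer(n_cmc)
  cfg <- structure(list(n_cmc = n_cmc,
                        sampling_frequency_hz = sampling_frequency_hz,
                        encoder_low = encoder_low, encoder_high = encoder_high,
                        seed = as.integer(seed),
                        sys = full_sys, dt = full_dt, motor = m,
                        plasticity = plasticity),
                   class = "cmc_config")
  validate_config(cfg)
  cfg
}

check_named <- function(x, allowed, what) {
  if (length(x) == 0) return(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop(what, " overrides must be named", call. = FALSE)
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown ", what, " names: ", paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Validate a simulation configuration
#'
#' Checks every module invariant (positive circuit count, sampling cap,
#' encoder ordering, non-negative SyS and DT, non-negative muscle strength
#' and gains, plasticity block well-formed).  Called by [sim_config()] and
#' again by the runners before a simulation starts.
#'
#' @param cfg A `cmc_config`.
#' @return `cfg`, invisibly; stops on violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cmc_config"))
  if (!is.numeric(cfg$n_cmc) || length(cfg$n_cmc) != 1 || cfg$n_cmc < 1 ||
      cfg$n_cmc != round(cfg$n_cmc))
    stop("n_cmc must be a positive integer", call. = FALSE)
  rate_coding_config(cfg$sampling_frequency_hz, cfg$encoder_low, cfg$encoder_high)
  sysv <- unlist(cfg$sys); dtv <- unlist(cfg$dt)
  if (any(sysv < 0)) stop("synaptic strengths must be >= 0", call. = FALSE)
  if (any(dtv < 0)) stop("depolarisation thresholds must be >= 0", call. = FALSE)
  m <- cfg$motor
  if (m$muscle_strength < 0) stop("muscle_strength must be >= 0", call. = FALSE)
  if (m$flexor_excitability < 0 || m$extensor_excitability < 0)
    stop("excitability gains must be >= 0", call. = FALSE)
  if (any(unlist(m$sys) < 0) || any(unlist(m$dt) < 0))
    stop("comparator SyS/DT must be >= 0", call. = FALSE)
  if (!is.null(cfg$plasticity)) stopifnot(inherits(cfg$plasticity, "plasticity_config"))
  invisible(cfg)
}

#' Materialise per-circuit synaptic parameters
#'
#' Expands the scalar SyS/DT values of a configuration into length-`n`
#' vectors, one entry per parallel micro-complex.  Stored as vectors even
#' when homogeneous because plasticity updates are applied per circuit.
#'
#' @param cfg A [sim_config()].
#' @param n Number of circuits (defaults to `cfg$n_cmc`).
#' @return An object of class `cmc_params` with fields `n`, `sys` (list of
#'   numeric vectors) and `dt` (list of numeric vectors).
#' @export
cmc_params <- function(cfg, n = cfg$n_cmc) {
  validate_config(cfg)
  structure(list(n = n,
                 sys = lapply(cfg$sys, rep_len, n),
                 dt  = lapply(cfg$dt, rep_len, n)),
            class = "cmc_params")
}

# Comparator-plant parameters, expanded per circuit like cmc_params().
motor_params <- function(cfg, n = cfg$n_cmc) {
  m <- cfg$motor
  structure(list(n = n,
                 sys = lapply(m$sys, rep_len, n),
                 dt  = lapply(m$dt, rep_len, n),
                 muscle_strength = m$muscle_strength,
                 force_on_joint = m$force_on_joint,
                 flexor_excitability = m$flexor_excitability,
                 extensor_excitability = m$extensor_excitability,
                 power_scale = m$power_scale),
            class = "motor_params")
}

#' @export
print.cmc_config <- function(x, ...) {
  cat("cerebellar micro-complex simulation config\n")
  cat("  n_cmc:", x$n_cmc, " sampling:", x$sampling_frequency_hz, "Hz\n")
  cat("  encoder: [", x$encoder_low, ",", x$encoder_high, "]  seed:", x$seed, "\n")
  hom <- function(v) if (length(unique(unlist(v))) == 1) unlist(v)[1] else "per-synapse"
  cat("  SyS:", hom(x$sys), " DT:", hom(x$dt), "\n")
  cat("  muscle strength:", x$motor$muscle_strength,
      " force:", x$motor$force_on_joint, "\n")
  cat("  plasticity:", if (is.null(x$plasticity)) "off" else "on", "\n")
  invisible(x)
}
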