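# One synaptic term of a Boolean update: each active presynaptic element
# contributes runif() * SyS; inactive elements contribute exactly 0 and
# consume no draw, so the RNG stream is well defined given the input states.
vnr_term <- function(active, sys) {
  out <- numeric(length(active))
  idx <- which(active == 1L)
  if (length(idx)) out[idx] <- stats::runif(length(idx)) * sys[idx]
  out
}

check_len <- function(n, ...) {
  lens <- vapply(list(...), length, integer(1))
  if (any(lens != n))
    stop("state vector length mismatch: expected ", n, call. = FALSE)
}

#' Empty micro-complex population state
#'
#' All neurons at rest; the Golgi feedback term (which acts with a
#' one-sample delay on the granule cells) starts at zero.
#'
#' @param n Number of parallel circuits.
#' @return An object of class `cmc_state`: integer 0/1 vectors
#'   `mossy_fibre`, `climbing_fibre`, `granule`, `golgi`, `interneuron`,
#'   `purkinje`, `dcn` and `golgi_prev`.
#' @export
cmc_state <- function(n) {
  z <- integer(n)
  structure(list(mossy_fibre = z, climbing_fibre = z, granule = z,
                 golgi = z, interneuron = z, purkinje = z, dcn = z,
                 golgi_prev = z),
            class = "cmc_state")
}

#' Boolean neuron updates of the micro-complex circuit
#'
#' Each update draws an independent uniform value per active synaptic term
#' per circuit, scales it by the synapse's SyS (negated for inhibitory
#' terms), sums the terms, and fires (1) when the sum strictly exceeds the
#' neuron's depolarisation threshold DT.  The circuit wiring is:
#'
#' * granule: mossy fibre excitation minus Golgi inhibition from the
#'   previous sample;
#' * Golgi and inhibitory interneuron: granule (parallel-fibre) excitation;
#' * Purkinje: granule and climbing-fibre excitation minus interneuron
#'   inhibition;
#' * DCN: mossy and climbing-fibre excitation minus Purkinje inhibition.
#'
#' With the default SyS 1.5 and DT 0.15, a single active excitatory term
#' fires with probability `1 - DT/SyS = 0.9`.
#'
#' @param mossy,climbing,granule,golgi_prev,interneuron,purkinje Integer
#'   0/1 state vectors, one element per circuit.
#' @param params A [cmc_params()] object.
#' @return Integer 0/1 vector of postsynaptic states.
#' @name circuit_steps
NULL

#' @rdname circuit_steps
#' @export
step_granule <- function(mossy, golgi_prev, params) {
  check_len(params$n, mossy, golgi_prev)
  drive <- vnr_term(mossy, params$sys$mf_granule) -
    vnr_term(golgi_prev, params$sys$golgi_granule)
  as.integer(drive > params$dt$granule)
}

#' @rdname circuit_steps
#' @export
step_golgi <- function(granule, params) {
  check_len(params$n, granule)
  as.integer(vnr_term(granule, params$sys$granule_golgi) > params$dt$golgi)
}

#' @rdname circuit_steps
#' @export
step_interneuron <- function(granule, params) {
  check_len(params$n, granule)
  as.integer(vnr_term(granule, params$sys$granule_ii) > params$dt$ii)
}

#' @rdname circuit_steps
#' @export
step_purkinje <- function(granule, climbing, interneuron, params) {
  check_len(params$n, granule, climbing, interneuron)
  drive <- vnr_term(granule, params$sys$granule_purkinje) +
    vnr_term(climbing, params$sys$cf_purkinje) -
    vnr_term(interneuron, params$sys$ii_purkinje)
  as.integer(drive > params$dt$purkinje)
}

#' @rdname circuit_steps
#' @export
step_dcn <- function(mossy, climbing, purkinje, params) {
  check_len(params$n, mossy, climbing, purkinje)
  drive <- vnr_term(mossy, params$sys$mf_dcn) +
    vnr_term(climbing, params$sys$cf_dcn) -
    vnr_term(purkinje, params$sys$purkinje_dcn)
  as.integer(drive > params$dt$dcn)
}

#' One full sample of the micro-complex population
#'
#' Executes the neuron updates in their fixed within-sample order
#' (granule, Golgi, interneuron, Purkinje, DCN), vectorised across all
#' parallel circuits.  The Golgi state of the previous sample inhibits the
#' granule cells; the returned state carries the new Golgi state forward as
#' `golgi_prev`.  RNG draws are consumed in this documented order (one
#' synaptic term at a time, active circuits in index order), so a run is
#' reproducible bit-for-bit given the seed and inputs.
#'
#' @param mossy,climbing Integer 0/1 afferent vectors for this sample
#'   (see [sample_afferent()]).
#' @param state A [cmc_state()] carrying `golgi_prev`.
#' @param params A [cmc_params()].
#' @return The updated `cmc_state`.
#' @examples
#' set.seed(1)
#' cfg <- sim_config(n_cmc = 8)
#' p <- cmc_params(cfg)
#' st <- step_cmc_population(sample_afferent(0.5, 8),
#'                           sample_afferent(0.5, 8), cmc_state(8), p)
#' st$dcn
#' @export
step_cmc_population <- function(mossy, climbing, state, params) {
  stopifnot(inherits(state, "cmc_state"))
  check_len(params$n, mossy, climbing)
  granule <- step_granule(mossy, state$golgi_prev, params)
  golgi <- step_golgi(granule, params)
  interneuron <- step_interneuron(granule, params)
  purkinje <- step_purkinje(granule, climbing, interneuron, params)
  dcn <- step_dcn(mossy, climbing, purkinje, params)
  structure(list(mossy_fibre = mossy, climbing_fibre = climbing,
                 granule = granule, golgi = golgi, interneuron = interneuron,
                 purkinje = purkinje, dcn = dcn, golgi_prev = golgi),
            class = "cmc_state")
}

#' Open-loop raster simulation of the micro-complex population
#'
#' Steps the memoryless engine for a series of samples with afferent firing
#' probabilities supplied directly (no motor loop), recording the Boolean
#' state of every neuron type.  Useful for raster plots, firing-rate
#' estimates and spectrogram inputs.
#'
#' @param mf_prob,cf_prob Mossy / climbing firing probabilities: scalars or
#'   per-sample vectors of length `samples`.
#' @param samples Number of time samples.
#' @param cfg A [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return List of integer matrices (`samples` rows, `n_cmc` columns) per
#'   neuron type, class `cmc_run`.
#' @examples
#' r <- run_cmc_rasters(0.5, 0.5, samples = 20, cfg = sim_config(n_cmc = 4))
#' colMeans(r$dcn)
#' @export
run_cmc_rasters <- function(mf_prob, cf_prob, samples, cfg, seed = cfg$seed) {
  validate_config(cfg)
  stopifnot(samples >= 1)
  mf_prob <- rep_len(mf_prob, samples)
  cf_prob <- rep_len(cf_prob, samples)
  set.seed(seed)
  n <- cfg$n_cmc
  params <- cmc_params(cfg)
  state <- cmc_state(n)
  types <- c("mossy_fibre", "climbing_fibre", "granule", "golgi",
             "interneuron", "purkinje", "dcn")
  out <- stats::setNames(lapply(types, function(.) matrix(0L, samples, n)), types)
  for (t in seq_len(samples)) {
    mossy <- sample_afferent(mf_prob[t], n)
    climbing <- sample_afferent(cf_prob[t], n)
    state <- step_cmc_population(mossy, climbing, state, params)
    for (ty in types) out[[ty]][t, ] <- state[[ty]]
  }
  structure(c(out, list(cfg = cfg, seed = seed)), class = "cmc_run")
}
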