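#' Pathology and intervention presets
#'
#' Pure transforms of a [sim_config()] reproducing the perturbations
#' studied with the model.  Each preset edits only the parameters named
#' below and validates the result; identity arguments return the
#' configuration unchanged.
#'
#' * `preset_neocerebellar()`: loss of functioning micro-complexes -
#'   overrides the circuit count only.
#' * `preset_ethanol()`: acute alcohol intoxication - multiplies the SyS of
#'   all GABAergic synapses (Golgi-to-granule, interneuron-to-Purkinje,
#'   Purkinje-to-DCN) by `gaba_factor` (>= 1) and of all glutamatergic
#'   synapses (both afferent pathways and every granule-cell efferent) by
#'   `glu_factor` (<= 1, the weaker effect).  Setting one factor to 1
#'   yields the single-transmitter arms.
#' * `preset_kcna1()`: Kv1.1 loss of function - basket/interneuron
#'   hyperexcitability modelled by scaling the interneuron DT down by
#'   `dt_ii_factor` in (0, 1).
#' * `preset_cacna1a()`: CaV2.1 channelopathy - scales the SyS of the
#'   CaV2.1-dependent synapse set (granule-cell efferents, climbing-fibre
#'   efferents, Purkinje-to-DCN) by 0.35 for the milder `"tottering"`
#'   variant (65% reduction in transmitter release) or 0.15 for the severe
#'   `"rocker"` variant (85% reduction).  The affected set is overridable.
#' * `preset_dcn_bias()`: tonic DCN (dis)inhibition for external-force
#'   compensation - adds `dt_dcn_delta` to the DCN threshold (positive
#'   lowers DCN firing, compensating a force toward extension; negative
#'   raises it).
#'
#' @param cfg A [sim_config()].
#' @param n_cmc Replacement circuit count.
#' @param gaba_factor,glu_factor Multiplicative SyS factors for GABAergic /
#'   glutamatergic synapses.
#' @param dt_ii_factor Multiplicative factor on the interneuron DT.
#' @param variant `"tottering"` or `"rocker"`.
#' @param synapses Synapse names affected by the CaV2.1 preset.
#' @param dt_dcn_delta Signed shift of the DCN threshold; the resulting DT
#'   must remain non-negative.
#' @return The transformed `cmc_config`.
#' @examples
#' cfg <- sim_config(n_cmc = 100)
#' preset_cacna1a(cfg, "tottering")$sys$granule_purkinje  # 1.5 * 0.35
#' @name perturbation_presets
NULL

#' @rdname perturbation_presets
#' @export
preset_neocerebellar <- function(cfg, n_cmc) {
  stopifnot(inherits(cfg, "cmc_config"), n_cmc >= 1)
  cfg$n_cmc <- as.integer(n_cmc)
  validate_config(cfg)
}

#' @rdname perturbation_presets
#' @export
preset_ethanol <- function(cfg, gaba_factor = 1.5, glu_factor = 0.8) {
  stopifnot(inherits(cfg, "cmc_config"), gaba_factor > 0, glu_factor > 0)
  if (gaba_factor < 1)
    warning("ethanol facilitates GABAergic transmission; gaba_factor < 1",
            call. = FALSE)
  if (glu_factor > 1)
    warning("ethanol weakly inhibits glutamatergic transmission; glu_factor > 1",
            call. = FALSE)
  for (s in .gabaergic_synapses) cfg$sys[[s]] <- cfg$sys[[s]] * gaba_factor
  for (s in .glutamatergic_synapses) cfg$sys[[s]] <- cfg$sys[[s]] * glu_factor
  validate_config(cfg)
}

#' @rdname perturbation_presets
#' @export
preset_kcna1 <- function(cfg, dt_ii_factor = 0.5) {
  stopifnot(inherits(cfg, "cmc_config"), dt_ii_factor > 0, dt_ii_factor <= 1)
  cfg$dt$ii <- cfg$dt$ii * dt_ii_factor
  validate_config(cfg)
}

#' @rdname perturbation_presets
#' @export
preset_cacna1a <- function(cfg, variant = c("tottering", "rocker"),
                           synapses = .cacna1a_synapses) {
  stopifnot(inherits(cfg, "cmc_config"))
  variant <- match.arg(variant)
  factor <- switch(variant, tottering = 1 - 0.65, rocker = 1 - 0.85)
  bad <- setdiff(synapses, .cmc_synapses)
  if (length(bad)) stop("unknown synapses: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (s in synapses) cfg$sys[[s]] <- cfg$sys[[s]] * factor
  validate_config(cfg)
}

#' @rdname perturbation_presets
#' @export
preset_dcn_bias <- function(cfg, dt_dcn_delta) {
  stopifnot(inherits(cfg, "cmc_config"))
  new_dt <- cfg$dt$dcn + dt_dcn_delta
  if (new_dt < 0)
    stop("DCN threshold would become negative", call. = FALSE)
  cfg$dt$dcn <- new_dt
  validate_config(cfg)
}
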