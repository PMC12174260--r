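# Synapses subject to activity-dependent modification.
.plastic_synapses <- c("mf_granule", "granule_purkinje", "cf_purkinje",
                       "mf_dcn", "purkinje_dcn")

#' Plasticity configuration
#'
#' Operationalises the qualitative LTP/LTD rule set: "high-frequency" and
#' "low-frequency" activity are classified from an exponential moving
#' average (EMA) of each neuron's firing, a triggered rule scales its
#' target SyS multiplicatively, and untriggered synapses relax
#' geometrically toward their baseline strength.
#'
#' Defaults are deliberately slow relative to the 250 Hz sampling so that
#' adaptation becomes visible within a few hundred samples: EMA smoothing
#' 0.05 (time constant about 20 samples), a 1% SyS change per triggering
#' sample, 0.1% relaxation per quiet sample, activity cutoffs 0.2 / 0.6,
#' and hard SyS bounds \[0.1, 5\].
#'
#' @param high_threshold,low_threshold EMA firing-probability cutoffs
#'   classifying activity as high / low (`0 <= low < high <= 1`).
#' @param step_fraction Fractional SyS change per triggering sample
#'   (`(1 + step)` for LTP, `(1 - step)` for LTD).
#' @param relax_rate Fractional return toward baseline per non-triggering
#'   sample, in `(0, 1]`.
#' @param sys_min,sys_max Hard bounds on any plastic SyS.
#' @param ema_alpha EMA smoothing constant in `(0, 1]`.
#' @return An object of class `plasticity_config`.
#' @export
plasticity_config <- function(high_threshold = 0.6, low_threshold = 0.2,
                              step_fraction = 0.01, relax_rate = 0.001,
                              sys_min = 0.1, sys_max = 5, ema_alpha = 0.05) {
  stopifnot(low_threshold >= 0, low_threshold < high_threshold,
            high_threshold <= 1,
            step_fraction > 0, step_fraction < 1,
            relax_rate > 0, relax_rate <= 1,
            sys_min >= 0, sys_max > sys_min,
            ema_alpha > 0, ema_alpha <= 1)
  structure(list(high_threshold = high_threshold,
                 low_threshold = low_threshold,
                 step_fraction = step_fraction, relax_rate = relax_rate,
                 sys_min = sys_min, sys_max = sys_max,
                 ema_alpha = ema_alpha),
            class = "plasticity_config")
}

#' Classify EMA activity as low, mid or high
#'
#' @param ema EMA firing probability (vectorised).
#' @param cfg A [plasticity_config()].
#' @return Character vector of `"low"`, `"mid"`, `"high"`.
#' @export
classify_activity <- function(ema, cfg) {
  stopifnot(all(ema >= 0), all(ema <= 1))
  ifelse(ema <= cfg$low_threshold, "low",
         ifelse(ema >= cfg$high_threshold, "high", "mid"))
}

#' Relax synaptic strengths toward baseline
#'
#' `sys + relax_rate * (baseline - sys)`: geometric convergence back to the
#' pre-plasticity value for synapses whose rule did not trigger this sample.
#'
#' @param sys,baseline Current and baseline strengths.
#' @param relax_rate Fractional step in `(0, 1]`.
#' @export
relax_to_baseline <- function(sys, baseline, relax_rate) {
  stopifnot(relax_rate > 0, relax_rate <= 1)
  sys + relax_rate * (baseline - sys)
}

# Per-circuit plasticity state: baseline SyS snapshot and EMA firing
# estimates for the neuron types referenced by the rules.
plasticity_state <- function(params, cfg) {
  z <- numeric(params$n)
  structure(list(baseline = params$sys[.plastic_synapses],
                 ema = list(mossy = z, climbing = z, granule = z,
                            purkinje = z, dcn = z)),
            class = "plasticity_state")
}

#' Apply one sample of the LTP/LTD rule set
#'
#' Updates the per-circuit EMA activity estimates with the current Boolean
#' state, evaluates the six rules independently per circuit, scales each
#' triggered target SyS, clips to the configured bounds, and relaxes every
#' untriggered plastic synapse toward baseline:
#'
#' 1. parallel-fibre and climbing-fibre co-activation (same-sample Boolean
#'    AND of granule and climbing states) - granule-to-Purkinje LTD;
#' 2. isolated high-frequency parallel-fibre activity (granule EMA high,
#'    climbing fibre silent this sample) - granule-to-Purkinje LTP;
#' 3. high-frequency mossy-fibre activity - mossy-to-granule LTP;
#' 4. high-frequency climbing-fibre activity - climbing-to-Purkinje LTP;
#' 5. low-frequency mossy-fibre activity - mossy-to-DCN LTD;
#' 6. DCN firing this sample with low-frequency Purkinje activity -
#'    Purkinje-to-DCN LTD.
#'
#' @param pstate A `plasticity_state` (created internally by
#'   [run_closed_loop()]).
#' @param params The current [cmc_params()]; plastic SyS vectors are
#'   modified per circuit.
#' @param state The [cmc_state()] for this sample.
#' @param cfg A [plasticity_config()].
#' @return List with updated `state` (plasticity) and `params`.
#' @export
plasticity_step <- function(pstate, params, state, cfg) {
  a <- cfg$ema_alpha
  e <- pstate$ema
  e$mossy    <- (1 - a) * e$mossy    + a * state$mossy_fibre
  e$climbing <- (1 - a) * e$climbing + a * state$climbing_fibre
  e$granule  <- (1 - a) * e$granule  + a * state$granule
  e$purkinje <- (1 - a) * e$purkinje + a * state$purkinje
  e$dcn      <- (1 - a) * e$dcn      + a * state$dcn
  pstate$ema <- e

  hi <- cfg$high_threshold; lo <- cfg$low_threshold
  trig <- list(
    granule_purkinje_ltd = state$granule == 1L & state$climbing_fibre == 1L,
    granule_purkinje_ltp = e$granule >= hi & state$climbing_fibre == 0L,
    mf_granule_ltp       = e$mossy >= hi,
    cf_purkinje_ltp      = e$climbing >= hi,
    mf_dcn_ltd           = e$mossy <= lo,
    purkinje_dcn_ltd     = state$dcn == 1L & e$purkinje <= lo)

  up <- 1 + cfg$step_fraction; down <- 1 - cfg$step_fraction
  apply_rule <- function(sys, baseline, ltp = NULL, ltd = NULL) {
    touched <- rep(FALSE, length(sys))
    if (!is.null(ltp)) { sys[ltp] <- sys[ltp] * up;   touched <- touched | ltp }
    if (!is.null(ltd)) { sys[ltd] <- sys[ltd] * down; touched <- touched | ltd }
    sys[!touched] <- relax_to_baseline(sys[!touched], baseline[!touched],
                                       cfg$relax_rate)
    pmin(cfg$sys_max, pmax(cfg$sys_min, sys))
  }

  s <- params$sys; b <- pstate$baseline
  s$granule_purkinje <- apply_rule(s$granule_purkinje, b$granule_purkinje,
                                   ltp = trig$granule_purkinje_ltp,
                                   ltd = trig$granule_purkinje_ltd)
  s$mf_granule  <- apply_rule(s$mf_granule, b$mf_granule,
                              ltp = trig$mf_granule_ltp)
  s$cf_purkinje <- apply_rule(s$cf_purkinje, b$cf_purkinje,
                              ltp = trig$cf_purkinje_ltp)
  s$mf_dcn      <- apply_rule(s$mf_dcn, b$mf_dcn, ltd = trig$mf_dcn_ltd)
  s$purkinje_dcn <- apply_rule(s$purkinje_dcn, b$purkinje_dcn,
                               ltd = trig$purkinje_dcn_ltd)
  params$sys <- s
  list(state = pstate, params = params)
}
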