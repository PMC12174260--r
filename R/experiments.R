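#' Load a simulation configuration from a YAML file
#'
#' Reads the structured-text configuration, applies the reference defaults
#' for absent keys, warns on unknown keys and validates the result.
#' Recognised keys: `n_cmc`, `sampling_frequency_hz`, `encoder_low`,
#' `encoder_high`, `seed`, `sys` (named map), `dt` (named map), `motor`
#' (map, with nested `sys`/`dt`), `plasticity` (map of
#' [plasticity_config()] fields, or `enabled: false`).
#'
#' @param path Path to a YAML file; an empty file yields pure defaults.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("n_cmc", "sampling_frequency_hz", "encoder_low", "encoder_high",
             "seed", "sys", "dt", "motor", "plasticity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  raw <- raw[intersect(names(raw), known)]
  plast <- NULL
  if (!is.null(raw$plasticity)) {
    p <- raw$plasticity
    enabled <- !identical(p$enabled, FALSE)
    p$enabled <- NULL
    if (enabled) plast <- do.call(plasticity_config, p)
  }
  raw$plasticity <- NULL
  do.call(sim_config, c(raw, list(plasticity = plast)))
}

#' Write a run manifest
#'
#' JSON record of the effective configuration, seed, package version and
#' wall time, sufficient to reproduce a run.
#'
#' @param cfg The [sim_config()] used.
#' @param seed The seed used.
#' @param path Output file.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, seed, path, extra = list()) {
  m <- c(list(package = "cmcsim",
              version = as.character(utils::packageVersion("cmcsim")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed,
              config = unclass_deep(cfg)),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Seeded experiment runners
#'
#' Reproduces each results pipeline at configurable scale and writes
#' columnar CSV outputs plus a JSON manifest to `out_dir`.  Available
#' experiments:
#'
#' * `"single_cmc"`: one circuit tracking a sinusoid open-loop; writes the
#'   rasters and moving-average firing rates of every neuron type.
#' * `"scfh"`: afferent-grid sweep via the analytic marginal; writes the
#'   long-format grid.
#' * `"cmc_loss"`: closed-loop sinusoid tracking across a descending
#'   circuit-count ladder; writes trajectories and tremor series.
#' * `"ethanol"`: the four intoxication arms (baseline, GABA-up, Glu-down,
#'   combined); writes trajectories with tremor and error summaries.
#' * `"force_compensation"`: constant external forces with and without a
#'   compensating DCN threshold bias; writes trajectories.
#' * `"adaptive"`: plasticity enabled, an external-force epoch switched on
#'   and off mid-run; writes the trajectory with population firing rates
#'   and mean plastic SyS per sample.
#'
#' Runs are reproducible: the same name, overrides and seed yield identical
#' outputs.
#'
#' @param name Experiment name (see above).
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param n_cmc Circuit count (ladder maximum for `"cmc_loss"`).
#' @param samples Samples per run.
#' @param overrides Named list applied over the default [sim_config()]
#'   arguments.
#' @return Invisibly, the list of files written.
#' @export
run_experiment <- function(name = c("single_cmc", "scfh", "cmc_loss",
                                    "ethanol", "force_compensation",
                                    "adaptive"),
                           out_dir = ".", seed = 1L, n_cmc = 10000,
                           samples = 2500, overrides = list()) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_cfg <- function(n) do.call(sim_config, utils::modifyList(
    list(n_cmc = n, seed = seed), overrides))
  files <- character()
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  cfg_used <- base_cfg(n_cmc)

  if (name == "single_cmc") {
    cfg <- base_cfg(1)
    desired <- trajectory_sinusoid(samples, cfg$sampling_frequency_hz)
    enc <- rate_coding_config(cfg$sampling_frequency_hz,
                              cfg$encoder_low, cfg$encoder_high)
    run <- run_cmc_rasters(encode_position(desired, enc),
                           encode_position(desired, enc), samples, cfg,
                           seed = seed)
    types <- c("mossy_fibre", "climbing_fibre", "granule", "golgi",
               "interneuron", "purkinje", "dcn")
    df <- data.frame(t = seq_len(samples), desired = desired)
    for (ty in types) {
      df[[ty]] <- run[[ty]][, 1]
      df[[paste0(ty, "_rate_hz")]] <-
        firing_rate_moving_average(run[[ty]][, 1], cfg$sampling_frequency_hz)
    }
    emit(df, "single_cmc.csv")
    cfg_used <- cfg
  } else if (name == "scfh") {
    cfg <- base_cfg(n_cmc)
    grid <- scfh_sweep(cfg, mf_probs = seq(0, 1, length.out = 21),
                       cf_probs = seq(0, 1, length.out = 21))
    emit(as.data.frame(grid), "scfh_grid.csv")
    emit(data.frame(cf_prob = grid$cf_probs, central_mf = grid$central_mf),
         "scfh_central_curve.csv")
    cfg_used <- cfg
  } else if (name == "cmc_loss") {
    ladder <- n_cmc / 10^(0:2)
    ladder <- ladder[ladder >= 1]
    for (n in ladder) {
      cfg <- base_cfg(as.integer(n))
      desired <- trajectory_sinusoid(samples, cfg$sampling_frequency_hz)
      run <- run_closed_loop(desired, cfg, seed = seed)
      run$tremor <- intention_tremor(run$actual)
      emit(run, sprintf("cmc_loss_n%d.csv", as.integer(n)))
    }
  } else if (name == "ethanol") {
    arms <- list(baseline = function(cfg) cfg,
                 gaba_up = function(cfg) preset_ethanol(cfg, 1.5, 1),
                 glu_down = function(cfg) preset_ethanol(cfg, 1, 0.8),
                 combined = function(cfg) preset_ethanol(cfg, 1.5, 0.8))
    summaries <- list()
    for (arm in names(arms)) {
      cfg <- arms[[arm]](base_cfg(n_cmc))
      desired <- trajectory_sinusoid(samples, cfg$sampling_frequency_hz)
      run <- run_closed_loop(desired, cfg, seed = seed)
      run$tremor <- intention_tremor(run$actual)
      emit(run, sprintf("ethanol_%s.csv", arm))
      summaries[[arm]] <- data.frame(arm = arm,
                                     median_tremor = stats::median(run$tremor),
                                     median_error = stats::median(run$error))
    }
    emit(do.call(rbind, summaries), "ethanol_summary.csv")
  } else if (name == "force_compensation") {
    arms <- list(
      gravity_uncompensated = list(force = -0.5, delta = 0),
      gravity_compensated = list(force = -0.5, delta = 0.05),
      antigravity_uncompensated = list(force = 0.5, delta = 0),
      antigravity_compensated = list(force = 0.5, delta = -0.05))
    for (arm in names(arms)) {
      cfg <- preset_dcn_bias(base_cfg(n_cmc), arms[[arm]]$delta)
      desired <- trajectory_sinusoid(samples, cfg$sampling_frequency_hz)
      run <- run_closed_loop(desired, cfg, seed = seed,
                             force = arms[[arm]]$force)
      emit(run, sprintf("force_%s.csv", arm))
    }
  } else if (name == "adaptive") {
    cfg <- base_cfg(n_cmc)
    if (is.null(cfg$plasticity)) cfg$plasticity <- plasticity_config()
    desired <- trajectory_sinusoid(samples, cfg$sampling_frequency_hz)
    third <- floor(samples / 3)
    force <- c(rep(0, third), rep(-0.5, third),
               rep(0, samples - 2 * third))
    run <- run_closed_loop(desired, cfg, seed = seed, force = force,
                           record_rates = TRUE)
    run$force <- force
    emit(run, "adaptive.csv")
    cfg_used <- cfg
  }

  manifest <- file.path(out_dir, paste0(name, "_manifest.json"))
  write_manifest(cfg_used, seed, manifest,
                 extra = list(experiment = name, samples = samples,
                              n_cmc = n_cmc))
  invisible(c(files, manifest))
}
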