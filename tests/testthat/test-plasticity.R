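make_state <- function(n, ...) {
  st <- cmc_state(n)
  mods <- list(...)
  for (f in names(mods)) st[[f]] <- rep(as.integer(mods[[f]]), length.out = n)
  st
}

test_that("activity classification respects the thresholds", {
  cfg <- plasticity_config(high_threshold = 0.8, low_threshold = 0.2)
  expect_identical(classify_activity(0, cfg), "low")
  expect_identical(classify_activity(1, cfg), "high")
  expect_identical(classify_activity(0.5, cfg), "mid")
  expect_identical(classify_activity(c(0.1, 0.2, 0.21, 0.8, 0.79), cfg),
                   c("low", "low", "mid", "high", "mid"))
})

test_that("relaxation moves strengths geometrically toward baseline", {
  expect_identical(relax_to_baseline(1.5, 1.5, 0.5), 1.5)
  expect_identical(relax_to_baseline(3, 1.5, 1), 1.5)
  expect_equal(relax_to_baseline(3, 1.5, 0.1), 2.85)
})

test_that("each rule modifies only its target synapse", {
  n <- 4
  cfg <- plasticity_config()
  params <- cmc_params(sim_config(n_cmc = n))
  ps <- cmcsim:::plasticity_state(params, cfg)
  # drive the mossy EMA high while everything else stays mid/low and silent
  ps$ema$mossy <- rep(0.9, n)
  ps$ema$granule <- rep(0.4, n)
  before <- params$sys
  upd <- plasticity_step(ps, params, make_state(n), cfg)
  after <- upd$params$sys
  # EMA decays slightly within the call (all states 0), still above threshold
  expect_true(all(after$mf_granule > before$mf_granule))
  for (s in c("granule_purkinje", "cf_purkinje", "purkinje_dcn"))
    expect_equal(after[[s]], before[[s]], tolerance = 1e-12)
  # mossy EMA 0.9 is not low, so no mossy-to-DCN LTD either
  expect_equal(after$mf_dcn, before$mf_dcn, tolerance = 1e-12)
})

test_that("parallel-fibre/climbing co-activation depresses their Purkinje synapse", {
  n <- 3
  cfg <- plasticity_config()
  params <- cmc_params(sim_config(n_cmc = n))
  ps <- cmcsim:::plasticity_state(params, cfg)
  ps$ema$mossy <- rep(0.4, n)      # keep mossy rules silent
  st <- make_state(n, granule = 1, climbing_fibre = 1)
  upd <- plasticity_step(ps, params, st, cfg)
  expect_equal(upd$params$sys$granule_purkinje,
               params$sys$granule_purkinje * (1 - cfg$step_fraction))
})

test_that("low mossy activity depresses the mossy-to-DCN synapse", {
  n <- 3
  cfg <- plasticity_config()
  params <- cmc_params(sim_config(n_cmc = n))
  ps <- cmcsim:::plasticity_state(params, cfg)
  upd <- plasticity_step(ps, params, make_state(n), cfg)  # EMA stays 0: low
  expect_equal(upd$params$sys$mf_dcn,
               params$sys$mf_dcn * (1 - cfg$step_fraction))
})

test_that("DCN firing with quiet Purkinje depresses the Purkinje-DCN synapse", {
  n <- 3
  cfg <- plasticity_config()
  params <- cmc_params(sim_config(n_cmc = n))
  ps <- cmcsim:::plasticity_state(params, cfg)
  ps$ema$mossy <- rep(0.4, n)
  st <- make_state(n, dcn = 1)
  upd <- plasticity_step(ps, params, st, cfg)
  expect_equal(upd$params$sys$purkinje_dcn,
               params$sys$purkinje_dcn * (1 - cfg$step_fraction))
  # but not when the Purkinje EMA is not low
  ps$ema$purkinje <- rep(0.5, n)
  upd2 <- plasticity_step(ps, params, st, cfg)
  expect_equal(upd2$params$sys$purkinje_dcn, params$sys$purkinje_dcn,
               tolerance = 1e-12)
})

test_that("strengths stay inside the configured bounds", {
  n <- 2
  cfg <- plasticity_config(step_fraction = 0.5, sys_min = 1, sys_max = 2)
  params <- cmc_params(sim_config(n_cmc = n))
  ps <- cmcsim:::plasticity_state(params, cfg)
  ps$ema$mossy <- rep(1, n)
  st <- make_state(n, mossy_fibre = 1)
  for (i in 1:10) {
    upd <- plasticity_step(ps, params, st, cfg)
    ps <- upd$state; params <- upd$params
    expect_true(all(params$sys$mf_granule <= 2))
    expect_true(all(params$sys$mf_granule >= 1))
  }
})

test_that("with no triggers the strengths converge back to baseline", {
  n <- 2
  cfg <- plasticity_config(relax_rate = 0.2)
  params <- cmc_params(sim_config(n_cmc = n))
  ps <- cmcsim:::plasticity_state(params, cfg)
  params$sys$granule_purkinje <- rep(3, n)   # displaced from baseline 1.5
  ps$ema$mossy <- rep(0.4, n)                # all rules silent
  st <- make_state(n)
  st$mossy_fibre <- rep(1L, n)               # keeps mossy EMA mid
  for (i in 1:60) {
    upd <- plasticity_step(ps, params, st, cfg)
    ps <- upd$state; params <- upd$params
    ps$ema$mossy <- rep(0.4, n)
    ps$ema$granule <- rep(0.4, n)
  }
  expect_equal(params$sys$granule_purkinje, rep(1.5, n), tolerance = 1e-4)
})

test_that("plasticity configuration rejects inconsistent settings", {
  expect_error(plasticity_config(high_threshold = 0.2, low_threshold = 0.6))
  expect_error(plasticity_config(step_fraction = 0))
  expect_error(plasticity_config(relax_rate = 0))
  expect_error(plasticity_config(ema_alpha = 1.5))
})
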