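base <- sim_config(n_cmc = 100)

test_that("presets are pure transforms with identity arguments", {
  expect_identical(preset_ethanol(base, 1, 1), base)
  expect_identical(preset_kcna1(base, 1), base)
  expect_identical(preset_dcn_bias(base, 0), base)
  expect_identical(preset_neocerebellar(base, 100), base)
  a <- preset_cacna1a(base, "tottering")
  b <- preset_cacna1a(base, "tottering")
  expect_identical(a, b)
})

test_that("micro-complex loss preset only changes the circuit count", {
  cfg <- preset_neocerebellar(base, 10)
  expect_identical(cfg$n_cmc, 10L)
  cfg$n_cmc <- base$n_cmc
  expect_identical(cfg, base)
  expect_silent(preset_neocerebellar(base, 1))
  expect_error(preset_neocerebellar(base, 0))
})

test_that("ethanol preset scales transmitter classes separately", {
  cfg <- preset_ethanol(base, 1.5, 0.8)
  for (s in c("golgi_granule", "ii_purkinje", "purkinje_dcn"))
    expect_equal(cfg$sys[[s]], 1.5 * 1.5)
  for (s in c("mf_granule", "mf_dcn", "cf_purkinje", "cf_dcn",
              "granule_golgi", "granule_ii", "granule_purkinje"))
    expect_equal(cfg$sys[[s]], 1.5 * 0.8)
  expect_warning(preset_ethanol(base, 0.5, 1), "facilitates")
  expect_warning(preset_ethanol(base, 1.5, 1.2), "inhibits")
})

test_that("CaV2.1 presets apply the reported release reductions", {
  tot <- preset_cacna1a(base, "tottering")
  roc <- preset_cacna1a(base, "rocker")
  affected <- c("granule_golgi", "granule_ii", "granule_purkinje",
                "cf_purkinje", "cf_dcn", "purkinje_dcn")
  for (s in affected) {
    expect_equal(tot$sys[[s]], 1.5 * 0.35)
    expect_equal(roc$sys[[s]], 1.5 * 0.15)
  }
  expect_equal(tot$sys$mf_granule, 1.5)  # mossy terminals unaffected
  expect_error(preset_cacna1a(base, "wobbler"))
  expect_error(preset_cacna1a(base, "rocker", synapses = "no_such"))
})

test_that("severe CaV2.1 variant deviates further from baseline DCN output", {
  # averaged over the afferent grid; the ordering is not pointwise because
  # the preset weakens excitatory climbing drive and Purkinje inhibition
  # of the DCN at once, and the two effects cancel differently per input
  p <- seq(0.1, 0.9, 0.2)
  grid <- expand.grid(mf = p, cf = p)
  d0 <- dcn_marginal(grid$mf, grid$cf, base)
  dt <- dcn_marginal(grid$mf, grid$cf, preset_cacna1a(base, "tottering"))
  dr <- dcn_marginal(grid$mf, grid$cf, preset_cacna1a(base, "rocker"))
  expect_gt(mean(abs(dr - d0)), mean(abs(dt - d0)))
  expect_gt(mean(abs(dt - d0)), 0)
})

test_that("interneuron-threshold preset disinhibits the DCN", {
  cfg <- preset_kcna1(base, 0.5)
  expect_equal(cfg$dt$ii, 0.075)
  # interneuron transfer rises when its threshold falls
  p_before <- firing_probability(threshold_problem(1.5, numeric(), 0.15))
  p_after <- firing_probability(threshold_problem(1.5, numeric(), 0.075))
  expect_gt(p_after, p_before)
  # population consequences at matched inputs: interneuron up, Purkinje
  # down, DCN up
  set.seed(30)
  n_cfg <- sim_config(n_cmc = 30000)
  r0 <- run_cmc_rasters(0.6, 0.4, 30, n_cfg, seed = 30)
  rk <- run_cmc_rasters(0.6, 0.4, 30, preset_kcna1(n_cfg, 0.5), seed = 30)
  expect_gt(mean(rk$interneuron), mean(r0$interneuron))
  expect_lt(mean(rk$purkinje), mean(r0$purkinje))
  expect_gt(mean(rk$dcn), mean(r0$dcn))
  expect_error(preset_kcna1(base, 0))
  expect_error(preset_kcna1(base, 1.2))
})

test_that("tonic DCN bias shifts output frequency in the expected direction", {
  up <- preset_dcn_bias(base, 0.05)
  expect_equal(up$dt$dcn, 0.2)
  expect_lt(dcn_marginal(0.5, 0.5, up), dcn_marginal(0.5, 0.5, base))
  dn <- preset_dcn_bias(base, -0.05)
  expect_gt(dcn_marginal(0.5, 0.5, dn), dcn_marginal(0.5, 0.5, base))
  expect_error(preset_dcn_bias(base, -0.2), "negative")
})

test_that("tremor under micro-complex loss exceeds the intact circuit", {
  meds <- sapply(1:3, function(s) {
    sapply(c(100, 10000), function(n) {
      cfg <- preset_neocerebellar(sim_config(n_cmc = 20000, seed = s), n)
      run <- run_closed_loop(trajectory_sinusoid(250), cfg, seed = s)
      stats::median(intention_tremor(run$actual))
    })
  })
  expect_true(all(meds[1, ] > meds[2, ]))
})
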