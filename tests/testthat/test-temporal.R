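test_that("decay factor follows the refractory/step ratio", {
  expect_equal(decay_factor(3, 2), 1 / 3)
  expect_identical(decay_factor(3, 3), 0)
  expect_equal(decay_factor(4, 2), 0.5)
  expect_error(decay_factor(3, 4), "refractory")
  expect_error(decay_factor(0, 1), "positive")
})

test_that("temporal config derives step, decay and lockout length", {
  tc <- temporal_config(500, 3)
  expect_identical(tc$step_ms, 2)
  expect_equal(tc$decay, 1 / 3)
  expect_identical(tc$refractory_samples, 1L)
  tc0 <- temporal_config(250, 4)
  expect_identical(tc0$decay, 0)
  expect_identical(tc0$refractory_samples, 0L)
  tc_ovr <- temporal_config(500, 3, decay = 2 / 3)
  expect_equal(tc_ovr$decay, 2 / 3)
})

test_that("subthreshold drive accumulates across samples (temporal summation)", {
  # two 0.12 drives with decay 2/3 cross DT = 0.15 on the second sample,
  # while 0.10 drives (either decay) do not
  s1 <- step_temporal_neuron(0.12, 0, 0L, 0.15, 2 / 3, 1L)
  expect_identical(s1$fired, 0L)
  expect_equal(s1$effect, 0.08)
  s2 <- step_temporal_neuron(0.12, s1$effect, s1$lock, 0.15, 2 / 3, 1L)
  expect_identical(s2$fired, 1L)
  # 0.10 drives with decay 1/3: 0.10/3 + 0.10 = 0.133 stays below DT
  a <- step_temporal_neuron(0.10, 0, 0L, 0.15, 1 / 3, 1L)
  b <- step_temporal_neuron(0.10, a$effect, a$lock, 0.15, 1 / 3, 1L)
  expect_identical(b$fired, 0L)
  # with decay 2/3 the carried 0.0667 pushes 0.1667 over DT = 0.15
  a2 <- step_temporal_neuron(0.10, 0, 0L, 0.15, 2 / 3, 1L)
  b2 <- step_temporal_neuron(0.10, a2$effect, a2$lock, 0.15, 2 / 3, 1L)
  expect_identical(b2$fired, 1L)
})

test_that("firing imposes the -1 effect and the refractory lockout", {
  s <- step_temporal_neuron(1.4, 0, 0L, 0.15, 1 / 3, 1L)
  expect_identical(s$fired, 1L)
  expect_equal(s$effect, -1 / 3)
  expect_identical(s$lock, 1L)
  # locked out next sample even under maximal drive
  s2 <- step_temporal_neuron(1.5, s$effect, s$lock, 0.15, 1 / 3, 1L)
  expect_identical(s2$fired, 0L)
  expect_identical(s2$lock, 0L)
  # free again on the sample after, given sufficient drive
  s3 <- step_temporal_neuron(1.4, s2$effect, s2$lock, 0.15, 1 / 3, 1L)
  expect_identical(s3$fired, 1L)
})

test_that("no drive leaves the membrane at rest", {
  s <- step_temporal_neuron(0, 0, 0L, 0.15, 1 / 3, 1L)
  expect_identical(s$fired, 0L)
  expect_identical(s$effect, 0)
})

test_that("silent afferents give a silent temporal raster", {
  cfg <- sim_config(n_cmc = 50, seed = 8)
  r <- run_temporal_cmc(0, 0, 100, cfg, temporal_config())
  for (ty in c("granule", "golgi", "interneuron", "purkinje", "dcn"))
    expect_identical(sum(r[[ty]]), 0L)
})

test_that("rasters never violate the refractory period and stay reproducible", {
  cfg <- sim_config(n_cmc = 300, seed = 13)
  tc <- temporal_config(500, 3)
  r <- run_temporal_cmc(0.3, 0.2, 400, cfg, tc)
  for (ty in c("granule", "golgi", "interneuron", "purkinje", "dcn"))
    expect_identical(refractory_violations(r[[ty]], 2L), 0L)
  r2 <- run_temporal_cmc(0.3, 0.2, 400, cfg, tc)
  expect_identical(r$dcn, r2$dcn)
})

test_that("zero decay with step >= refractory reproduces the memoryless engine", {
  cfg <- sim_config(n_cmc = 80, seed = 17)
  tc0 <- temporal_config(250, 4)
  rt <- run_temporal_cmc(0.5, 0.3, 150, cfg, tc0)
  rn <- run_cmc_rasters(0.5, 0.3, 150, cfg)
  for (ty in c("mossy_fibre", "climbing_fibre", "granule", "golgi",
               "interneuron", "purkinje", "dcn"))
    expect_identical(rt[[ty]], rn[[ty]])
})

test_that("temporal and memoryless engines agree at matched input rates", {
  cfg <- sim_config(n_cmc = 500, seed = 2)
  tc <- temporal_config(500, 3)
  rN <- run_cmc_rasters(50 / 250, 25 / 250, 400, cfg, seed = 3)
  rT <- run_temporal_cmc(50 / 500, 25 / 500, 800, cfg, tc, seed = 3)
  for (ty in c("granule", "golgi", "interneuron", "purkinje", "dcn")) {
    fN <- mean(rN[[ty]]) * 250
    fT <- mean(rT[[ty]]) * 500
    expect_lt(abs(fT - fN) / fN, 0.2)
  }
})

test_that("carried effect stays bounded in [-1, 1]", {
  set.seed(99)
  eff <- 0; lock <- 0L
  for (i in 1:500) {
    s <- step_temporal_neuron(runif(1, -2, 2), eff, lock, 0.5, 0.9, 1L)
    eff <- s$effect; lock <- s$lock
    expect_true(eff >= -1 && eff <= 1)
  }
})
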