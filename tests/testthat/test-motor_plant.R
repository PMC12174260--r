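mpar_n <- function(n, ...) cmcsim:::motor_params(sim_config(n_cmc = n, ...))

test_that("muscle power is the scaled population vote plus the external force", {
  mp <- mpar_n(1000)
  expect_identical(muscle_power(rep(1L, 1000), integer(1000), mp), 10)
  flex <- sample(0:1, 1000, replace = TRUE)
  expect_identical(muscle_power(flex, flex, mp), 0)
  expect_identical(muscle_power(flex, flex, mp, force = 0.3), 0.3)
  v <- muscle_power(rep(c(1L, 0L), c(600, 400)),
                    rep(c(0L, 1L), c(600, 400)), mp)
  expect_equal(v, 2)
  expect_error(muscle_power(integer(0), integer(0), mp), "at least one")
})

test_that("diagnostic motor-minus-DCN power mirrors the operative formula", {
  mp <- mpar_n(1000)
  expect_identical(simple_muscle_power(rep(1L, 1000), integer(1000), mp), 10)
  expect_equal(simple_muscle_power(rep(c(1L, 0L), c(600, 400)),
                                   rep(c(0L, 1L), c(600, 400)), mp), 2)
})

test_that("joint position integrates power and clamps to [0, 1]", {
  expect_identical(update_joint(0.5, 0), 0.5)
  expect_identical(update_joint(0.9, 0.3), 1)
  expect_identical(update_joint(0.1, -0.3), 0)
  expect_equal(update_joint(0.5, -0.2), 0.3)
})

test_that("movement error is the absolute position difference", {
  expect_identical(movement_error(0.5, 0.5), 0)
  expect_equal(movement_error(0.2, 0.7), 0.5)
  expect_identical(movement_error(1, 0), 1)
})

test_that("comparator is quiescent without input and matches closed forms", {
  set.seed(11)
  n <- 100000
  mp <- mpar_n(n)
  z <- integer(n); on <- rep(1L, n)
  comp0 <- step_comparator(z, z, mp)
  for (f in c("p1", "p2", "p3", "flexor", "extensor_in", "extensor"))
    expect_identical(comp0[[f]], z)
  comp <- step_comparator(on, on, mp)
  expect_true(within_3se(mean(comp$p1), 0.405, n))
  expect_true(within_3se(mean(comp$p2), 0.405, n))
})

test_that("motor-only drive favours the flexor; DCN-only drive the extensor", {
  set.seed(12)
  n <- 100000
  mp <- mpar_n(n)
  z <- integer(n); on <- rep(1L, n)
  follow <- step_comparator(z, on, mp)     # only the motor signal active
  expect_gt(mean(follow$flexor), mean(follow$extensor))
  oppose <- step_comparator(on, z, mp)     # only the DCN active
  expect_gt(mean(oppose$extensor), mean(oppose$flexor))
})

test_that("trajectory generators stay inside the position range", {
  d <- trajectory_sinusoid(500)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d[1], 0.5)
  expect_error(trajectory_sinusoid(100, offset = 0.8, amplitude = 0.5),
               "range")
  expect_identical(trajectory_constant(10, 0.3), rep(0.3, 10))
  expect_identical(trajectory_steps(c(0.2, 0.8), c(2, 3)),
                   c(0.2, 0.2, 0.8, 0.8, 0.8))
})

test_that("closed loop is deterministic given seed and config", {
  cfg <- sim_config(n_cmc = 300, seed = 21)
  a <- run_closed_loop(trajectory_sinusoid(120), cfg)
  b <- run_closed_loop(trajectory_sinusoid(120), cfg)
  expect_identical(a, b)
})

test_that("zero muscle strength freezes the joint", {
  cfg <- sim_config(n_cmc = 200, seed = 3,
                    motor = list(muscle_strength = 0))
  run <- run_closed_loop(trajectory_sinusoid(100), cfg)
  expect_true(all(run$actual == run$actual[1]))
})

test_that("power magnitude never exceeds the configured bound", {
  cfg <- sim_config(n_cmc = 500, seed = 4)
  run <- run_closed_loop(trajectory_sinusoid(200), cfg, force = 0.25)
  bound <- cfg$motor$muscle_strength * cfg$motor$power_scale + 0.25
  expect_true(all(abs(run$muscle_power) <= bound))
  expect_equal(run$error, abs(run$actual - run$desired))
})

test_that("the flexor/extensor vote is a restoring force around its equilibrium", {
  # net drive positive when the joint is far below target, negative far above
  set.seed(33)
  n <- 50000
  cfg <- sim_config(n_cmc = n)
  params <- cmc_params(cfg)
  mp <- cmcsim:::motor_params(cfg)
  net_at <- function(actual, desired) {
    st <- cmc_state(n)
    for (i in 1:8) {
      mossy <- sample_afferent(actual, n)
      climbing <- sample_afferent(desired, n)
      st <- step_cmc_population(mossy, climbing, st, params)
    }
    comp <- step_comparator(st$dcn, climbing, mp)
    mean(comp$flexor - comp$extensor)
  }
  expect_gt(net_at(0.0, 0.5), 0)
  expect_lt(net_at(1.0, 0.5), 0)
})

test_that("tracking degrades monotonically as circuits are removed", {
  seeds <- 1:3
  meds <- sapply(seeds, function(s) {
    sapply(c(100, 1000, 10000), function(n) {
      cfg <- sim_config(n_cmc = n, seed = s)
      run <- run_closed_loop(trajectory_sinusoid(300), cfg)
      stats::median(log10(intention_tremor(run$actual) + 1e-12))
    })
  })
  # per-seed ordering across the circuit ladder
  expect_true(all(meds[1, ] > meds[2, ]))
  expect_true(all(meds[2, ] > meds[3, ]))
})
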