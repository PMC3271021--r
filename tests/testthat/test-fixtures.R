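test_that("default experiment states the reference batch conditions", {
  ex <- default_experiment()
  expect_equal(ex$params[["mu_max_L"]], 0.57)
  expect_equal(ex$params[["t_L"]], 7.10)
  expect_equal(unname(ex$init["LACT"]), 30)
  expect_equal(unname(ex$init["X"]), 0.001)
  expect_length(ex$schedule, 35) # hourly, inclusive, over 34 h
  expect_equal(ex$noise, 0.02)
})

test_that("synthetic measurements are exact at zero noise and seeded", {
  ex <- default_experiment()
  m0 <- generate_noisy_batch(ex$params, ex$init, ex$schedule, noise = 0)
  traj <- simulate_batch(ex$params, ex$init, times = ex$schedule)
  expect_equal(m0$series$LACT$value, traj$LACT, tolerance = 1e-10)
  expect_equal(m0$series$X$value, traj$X, tolerance = 1e-10)
  m1 <- generate_noisy_batch(ex$params, ex$init, ex$schedule,
                             noise = 0.02, seed = 9)
  m2 <- generate_noisy_batch(ex$params, ex$init, ex$schedule,
                             noise = 0.02, seed = 9)
  expect_identical(m1, m2)
  expect_false(identical(
    m1, generate_noisy_batch(ex$params, ex$init, ex$schedule,
                             noise = 0.02, seed = 10)))
})

test_that("noise level scales with the variable maximum", {
  ex <- default_experiment()
  sched <- c(0, 20, 24) # away from zero, so truncation is inactive
  draws <- vapply(1:200, function(s) {
    m <- generate_noisy_batch(ex$params, ex$init, sched, noise = 0.02,
                              seed = s)
    m$series$LACT$value[2]
  }, 1)
  traj <- simulate_batch(ex$params, ex$init, times = sched)
  expect_lt(abs(sd(draws) / (0.02 * max(traj$LACT)) - 1), 0.25)
  expect_lt(abs(mean(draws) - traj$LACT[2]), 0.02 * 30 * 3 / sqrt(200))
})

test_that("the reference trajectory reproduces the batch phenology", {
  ex <- default_experiment()
  tr <- simulate_batch(ex$params, ex$init, horizon = 34, step = 0.1)
  # lactate exhausted between 25 and 30 h
  t_dep <- min(tr$time_h[tr$LACT < 0.5])
  expect_gt(t_dep, 25); expect_lt(t_dep, 30)
  # overflow products rise and then fall
  for (v in c("ACT", "PYR")) {
    peak <- which.max(tr[[v]])
    expect_gt(peak, 2); expect_lt(peak, nrow(tr))
    expect_gt(tr[[v]][peak], tr[[v]][nrow(tr)])
  }
  # biomass still increasing after lactate depletion
  late <- tr$time_h >= t_dep
  expect_gt(tr$X[nrow(tr)], tr$X[which(late)[1]])
})
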