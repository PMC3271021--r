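test_that("lag gate is a unit step at t_L", {
  expect_equal(lag_gate(3, 7.10), 0)
  expect_equal(lag_gate(7.10, 7.10), 1) # S = 1 exactly at the lag time
  expect_equal(lag_gate(20, 7.10), 1)
  expect_equal(lag_gate(c(0, 7.09, 7.11), 7.10), c(0, 0, 1))
})

test_that("specific growth rates follow saturation kinetics", {
  p <- mr1_kinetics()
  st <- c(X = 0.1, LACT = 19.4, ACT = 0, PYR = 0)
  mu <- specific_growth_rates(st, p)
  expect_equal(mu[["mu_L"]], 0.57 / 2) # half-saturation
  expect_equal(mu[["mu_A"]], 0)
  st2 <- c(X = 0.1, LACT = 30, ACT = 0, PYR = 0)
  expect_equal(specific_growth_rates(st2, p)[["mu_L"]],
               0.57 * 30 / (19.4 + 30), tolerance = 1e-12)
  expect_equal(specific_growth_rates(c(X = 1, LACT = 0, ACT = 0, PYR = 0),
                                     p)[["mu_L"]], 0)
})

test_that("growth rate on lactate is increasing and bounded by mu_max", {
  p <- mr1_kinetics()
  lact <- seq(0.1, 200, length.out = 80)
  mu <- vapply(lact, function(l)
    specific_growth_rates(c(X = 1, LACT = l, ACT = 0, PYR = 0), p)[["mu_L"]],
    1)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu < p[["mu_max_L"]]))
})

test_that("overflow rates are first order in biomass and substrate", {
  p <- mr1_kinetics()
  expect_equal(unname(overflow_rates(c(X = 0, LACT = 20, ACT = 0, PYR = 5),
                                     p)), c(0, 0, 0))
  r <- overflow_rates(c(X = 0.1, LACT = 20, ACT = 0, PYR = 0), p)
  expect_equal(r[["r_AL"]], 0.71 * 0.1 * 20) # 1.42 mmol/L/h
  r2 <- overflow_rates(c(X = 0.1, LACT = 0, ACT = 0, PYR = 5), p)
  expect_equal(r2[["r_AL"]], 0)
  expect_equal(r2[["r_PL"]], 0)
  expect_gt(r2[["r_AP"]], 0)
})

test_that("state derivatives implement the gated batch ODEs", {
  p <- mr1_kinetics()
  st <- c(X = 0.05, LACT = 29, ACT = 0, PYR = 0)
  # before the lag everything is frozen
  expect_equal(unname(monod_rhs(3, st, p)), rep(0, 4))
  d <- monod_rhs(10, st, p)
  expect_equal(d[["X"]], (0.57 * 29 / 48.4 - 0.013) * 0.05,
               tolerance = 1e-12)
  # no consumption of an absent product: dACT/dt is pure production
  expect_equal(d[["ACT"]], sum(overflow_rates(st, p)[c("r_AL", "r_AP")]))
  expect_gte(d[["ACT"]], 0)
  expect_lt(d[["LACT"]], 0)
})

test_that("batch simulation honours degenerate and scaling limits", {
  z <- stats::setNames(rep(0, 14), monod_param_names())
  z[c("Y_XL", "Y_XA", "Y_XP")] <- 1
  p0 <- as_monod_params(z)
  tr <- simulate_batch(p0, init = c(X = 0.2, LACT = 10, ACT = 1, PYR = 2),
                      horizon = 5, step = 0.5)
  expect_true(all(abs(tr$X - 0.2) < 1e-10))
  expect_true(all(abs(tr$LACT - 10) < 1e-10))
  # with zero growth/overflow parameters, doubling X0 doubles X everywhere
  tr2 <- simulate_batch(p0, init = c(X = 0.4, LACT = 10, ACT = 1, PYR = 2),
                        horizon = 5, step = 0.5)
  expect_equal(tr2$X, 2 * tr$X, tolerance = 1e-10)
})

test_that("lactate is non-increasing and states non-negative", {
  tr <- simulate_batch(mr1_kinetics(), horizon = 34, step = 0.1)
  post <- tr$time_h >= 7.10
  expect_true(all(diff(tr$LACT[post]) <= 1e-9))
  expect_true(all(as.matrix(tr[, -1]) >= 0))
  expect_equal(unname(unlist(tr[1, -1])), c(0.001, 30, 0, 0))
})

test_that("carbon-weighted concentration cannot grow without growth", {
  # k_e = 0 and effectively infinite yields: only overflow conversions
  # remain, and 3 LACT + 3 PYR + 2 ACT loses one carbon per acetate made
  p <- mr1_kinetics()
  p[c("Y_XL", "Y_XA", "Y_XP")] <- 1e12
  p["k_e"] <- 0
  tr <- simulate_batch(p, init = c(X = 0.1, LACT = 30, ACT = 0, PYR = 0),
                       horizon = 20, step = 0.25)
  carbon <- 3 * tr$LACT + 3 * tr$PYR + 2 * tr$ACT
  expect_true(all(diff(carbon) <= 1e-6))
})

test_that("normalized residual matches its definition", {
  p <- mr1_kinetics()
  m <- clean_measurements_fx()
  expect_lt(normalized_residual(p, m), 1e-10)
  # one observation off by exactly its normalization constant adds 1
  m1 <- m
  m1$series$LACT$value[10] <- m1$series$LACT$value[10] + m1$norm[["LACT"]]
  m1 <- as_batch_measurements(
    data.frame(time_h = m1$series$LACT$time, LACT = m1$series$LACT$value))
  # rebuild with the original normalization to isolate the definition
  m1$norm[["LACT"]] <- m$norm[["LACT"]]
  expect_equal(normalized_residual(p, m1), 1, tolerance = 1e-6)
})

test_that("each variable contributes on its own normalized scale", {
  # two variables each off by half their norm at one point: R = 2 * 0.25
  p <- mr1_kinetics()
  m <- clean_measurements_fx()
  m2 <- m
  m2$series$LACT$value[12] <- m2$series$LACT$value[12] +
    m2$norm[["LACT"]] / 2
  m2$series$ACT$value[20] <- m2$series$ACT$value[20] - m2$norm[["ACT"]] / 2
  expect_equal(normalized_residual(p, m2), 0.5, tolerance = 1e-6)
})
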