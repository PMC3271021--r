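test_that("discretization follows the floor rule", {
  expect_length(discretize(34, 5 / 60), 409) # 408 intervals
  expect_length(discretize(1, 1), 2)
  expect_warning(b <- discretize(1, 0.4), "partial")
  expect_length(b, 3) # two whole intervals, remainder dropped
})

test_that("exchange fluxes are specific rates from the kinetics", {
  p <- mr1_kinetics()
  traj <- simulate_batch(p, horizon = 34, step = 0.05)
  ec <- compute_exchange_fluxes(traj, 20, p)
  st <- trajectory_state(traj, 20)[1, ]
  d <- monod_rhs(20, st, p)
  expect_equal(ec$v_lac_inflow, -d[["LACT"]] / st[["X"]], tolerance = 1e-9)
  expect_equal(ec$v_act_flow, d[["ACT"]] / st[["X"]], tolerance = 1e-9)
  expect_gt(ec$v_lac_inflow, 0)
  # 0.1 g/L consuming 3 mM/h takes up 30 mmol/g DCW/h: scale check
  expect_equal(exchange_constraints(30, 0, 0)$v_lac_inflow,
               -(-3.0) / 0.1)
  # late phase: acetate is taken up, not secreted
  ec_late <- compute_exchange_fluxes(traj, 31, p)
  expect_lt(ec_late$v_act_flow, 0)
  # no biomass, no specific rate
  traj0 <- simulate_batch(p, init = c(X = 0, LACT = 30, ACT = 0, PYR = 0),
                          horizon = 10, step = 1)
  expect_error(compute_exchange_fluxes(traj0, 5, p), "no biomass")
})

test_that("weight fitting tracks the monotone response curve", {
  toy <- toy_model_fx()
  ec <- exchange_constraints(30.5, 12.3, 7.8)
  grid <- c(0, pracma::logseq(1e-9, 1, 30))
  mu0 <- solve_fba_max_growth(toy, ec)$mu
  # target exactly the LP optimum: smallest weight, zero residual
  fw <- fit_weight(toy, ec, mu0, grid)
  expect_equal(fw$w, 0)
  expect_lt(fw$residual, 1e-9)
  # unattainable growth warns and returns the smallest weight
  expect_warning(fw2 <- fit_weight(toy, ec, mu0 * 1.5, grid),
                 "unattainable")
  expect_equal(fw2$w, 0)
  expect_gt(fw2$residual, 0)
  # half the LP optimum: some positive weight, residual within the local
  # grid resolution (checked against the full response curve)
  target <- 0.5 * mu0
  fw3 <- fit_weight(toy, ec, target, grid)
  expect_gt(fw3$w, 0)
  curve <- growth_response_curve(toy, ec, grid)
  resid_all <- abs(curve$mu - target)
  expect_equal(fw3$residual, min(resid_all), tolerance = 1e-9)
  i <- which.min(resid_all)
  gap <- abs(diff(curve$mu[max(1, i - 1):min(nrow(curve), i + 1)]))
  expect_lte(fw3$residual, max(gap))
})

test_that("a coarse dynamic run conserves structure", {
  run <- coarse_run_fx()
  iv <- run$intervals
  expect_equal(nrow(iv), 68) # floor(34 / 0.5)
  expect_equal(run$n_failed, 0L)
  expect_true(all(diff(iv$t_mid) > 0))
  # steady state in every recorded interval
  toy <- run$model
  rel <- vapply(seq_len(nrow(iv)), function(i) {
    v <- run$fluxes[i, ]
    if (max(abs(v)) == 0) return(0)
    max(abs(toy$S %*% v)) / max(abs(v))
  }, 1)
  expect_lt(max(rel), 1e-8)
  # biomass increments sum to the net biomass formed
  X <- trajectory_state(run$trajectory, c(0, 34))[, "X"]
  expect_equal(sum(iv$dX), diff(X), tolerance = 1e-9)
  # before the lag nothing grows and nothing is exchanged
  pre <- iv$t_mid < 7
  expect_true(all(iv$mu_monod[pre] == 0))
  expect_true(all(abs(iv$v_lac_inflow[pre]) < 1e-12))
})

test_that("flux ratios handle zero denominators as NaN", {
  run <- coarse_run_fx()
  fr <- flux_ratio_series(run, "MALS", "FUM")
  expect_equal(nrow(fr), nrow(run$intervals))
  self <- flux_ratio_series(run, "FUM", "FUM")
  defined <- !is.nan(self$ratio)
  expect_true(all(abs(self$ratio[defined] - 1) < 1e-12))
  pre <- run$intervals$t_mid < 7 # all-zero fluxes: NaN, not an error
  expect_true(all(is.nan(fr$ratio[pre])))
  expect_error(flux_ratio_series(run, "NOPE", "FUM"), "unknown reaction")
})

test_that("halving the interval changes integrated uptake by little", {
  run1 <- coarse_run_fx()
  run2 <- run_dfba(toy_model_fx(), mr1_kinetics(),
                   cfg = dfba_config(dt = 0.25))
  uptake <- function(run) {
    X <- trajectory_state(run$trajectory, run$intervals$t_mid)[, "X"]
    sum(run$intervals$v_lac_inflow * X * run$cfg$dt)
  }
  u1 <- uptake(run1); u2 <- uptake(run2)
  expect_lt(abs(u1 - u2) / u2, 0.02)
  # and the total should be close to the lactate actually consumed
  lact <- trajectory_state(run2$trajectory, c(0, 34))[, "LACT"]
  expect_lt(abs(u2 - (lact[1] - lact[2])) / 30, 0.02)
})

test_that("dFBA outputs round-trip through the TSV directory format", {
  run <- coarse_run_fx()
  d <- withr::local_tempdir()
  write_dfba_tsv(run, d)
  expect_setequal(list.files(d),
                  c("fluxes.tsv", "weights.tsv", "constraints.tsv"))
  wt <- utils::read.table(file.path(d, "weights.tsv"), header = TRUE,
                          sep = "\t")
  expect_equal(nrow(wt), 68)
  expect_equal(wt$w_star, run$intervals$w_star, tolerance = 1e-12)
})
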