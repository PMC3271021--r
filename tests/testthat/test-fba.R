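test_that("zero carbon supply means zero growth", {
  sol <- solve_fba_max_growth(toy_model_fx(), exchange_constraints(0, 0, 0))
  expect_equal(sol$status, "optimal")
  expect_lt(abs(sol$mu), 1e-6)
})

test_that("w = 0 reduces the dual objective to the max-growth LP", {
  toy <- toy_model_fx()
  ec <- exchange_constraints(10, 0, 0)
  lp <- solve_fba_max_growth(toy, ec)
  dual0 <- solve_dual_objective(toy, ec, w = 0)
  expect_lt(abs(lp$mu - dual0$mu), 1e-6)
})

test_that("growth and total squared flux are non-increasing in w", {
  toy <- toy_model_fx()
  ec <- exchange_constraints(30.5, 12.3, 7.8)
  grid <- c(0, 10^seq(-9, 0, length.out = 12))
  curve <- growth_response_curve(toy, ec, grid)
  expect_true(all(curve$status == "optimal"))
  expect_true(all(diff(curve$mu) <= 1e-6))
  expect_true(all(diff(curve$sum_sq) <= 1e-4))
})

test_that("very large w approaches the minimum-norm feasible flux", {
  toy <- toy_model_fx()
  ec <- exchange_constraints(10, 2, 1)
  big <- solve_dual_objective(toy, ec, w = 1e6)
  # independent minimum-norm point: growth term removed entirely
  sys <- dynafba:::fba_system(toy, ec)
  v_min <- dynafba:::qp_point(sys, w = 1, d = rep(0, sys$n))
  expect_lt(max(abs(big$flux - v_min)), 1e-4)
})

test_that("doubling exchange magnitudes at most doubles growth", {
  toy <- toy_model_fx()
  ec1 <- exchange_constraints(10, 2, 1)
  ec2 <- exchange_constraints(20, 4, 2)
  mu1 <- solve_fba_max_growth(toy, ec1)$mu
  mu2 <- solve_fba_max_growth(toy, ec2)$mu
  expect_lte(mu2, 2 * mu1 + 1e-6)
})

test_that("infeasible exchange constraints are reported, not crashed", {
  toy <- toy_model_fx()
  # demand acetate secretion with no carbon input
  sol <- solve_dual_objective(toy, exchange_constraints(0, 50, 0), 1e-4)
  expect_equal(sol$status, "infeasible")
  expect_match(sol$violation, "EX_ac")
  expect_warning(
    curve <- growth_response_curve(toy, exchange_constraints(0, 50, 0),
                                   c(0, 1e-4)),
    "infeasible")
  expect_true(all(curve$status == "infeasible"))
})

test_that("single-point weight grid gives a single LP row", {
  curve <- growth_response_curve(toy_model_fx(),
                                 exchange_constraints(10, 0, 0), 0)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$w, 0)
})

test_that("dual-objective QP matches brute-force polytope search", {
  mm <- micro_model()
  ec <- exchange_constraints(10, NA, NA) # only the uptake is fixed
  # free coordinates (R2, BIO); balances give R1 and the waste flux R3
  grid <- expand.grid(R2 = seq(0, 8, length.out = 641),
                      BIO = seq(0, 10, length.out = 801))
  R1 <- 10 - grid$R2 - 0.6 * grid$BIO
  R3 <- 10 - grid$BIO
  ok <- R1 >= 0 & R1 <= 8 & R3 >= 0
  ssq <- 100 + R1^2 + grid$R2^2 + R3^2 + grid$BIO^2
  for (w in c(1e-4, 0.05, 0.2)) {
    obj <- grid$BIO - w * ssq
    best <- max(obj[ok])
    sol <- solve_dual_objective(mm, ec, w)
    expect_equal(sol$status, "optimal")
    got <- sol$mu - w * sol$sum_sq
    expect_gte(got, best - 1e-9)     # the grid can never beat the QP
    expect_lt(abs(got - best), 1e-3) # and confirms it to fine resolution
  }
  # max-growth LP against the brute-force maximum
  lp <- solve_fba_max_growth(mm, ec)
  expect_lt(abs(lp$mu - max(grid$BIO[ok])), 1e-3)
})
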