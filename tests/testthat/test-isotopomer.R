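test_that("isotopomer mapping matrices do positional bookkeeping", {
  am <- parse_atom_maps(text = c("IDX: A[abc] -> B[abc]",
                                 "PDH: pyr[abc] -> co2[a] + accoa[bc]"))
  ident <- build_imm(am$transitions[[1]], "A", "B")
  expect_equal(ident, diag(1L, 8), ignore_attr = TRUE)
  imm <- build_imm(am$transitions[[2]], "pyr", "accoa")
  expect_equal(dim(imm), c(4L, 8L))
  expect_true(all(colSums(imm) == 1))
  # substrate (0,0,1) -> product (0,1): index 5 -> index 3
  expect_equal(which(imm[, 5] == 1), 3L)
  co2 <- build_imm(am$transitions[[2]], "pyr", "co2")
  expect_equal(which(co2[, 2] == 1), 2L) # C1 label goes to CO2
})

test_that("atom-map parsing validates carbon bookkeeping", {
  expect_error(parse_atom_maps(text = "R: A[ab] -> B[abc]"),
               "carbon not conserved")
  expect_error(parse_atom_maps(text = "R: A[aa] -> B[aa]"),
               "duplicate")
  am <- parse_atom_maps(text = c("S1: A[ab] -> B[ab]",
                                 "S1: A[ab] -> B[ba]"))
  expect_equal(vapply(am$transitions, `[[`, 0, "weight"), c(0.5, 0.5))
  f <- withr::local_tempfile(fileext = ".txt")
  write_atom_maps(am, f)
  am2 <- parse_atom_maps(f)
  expect_equal(am2$transitions, am$transitions)
})

test_that("IDV to MDV collapse counts labeled carbons", {
  expect_equal(idv_to_mdv(c(1, 0, 0, 0)), c(1, 0, 0))
  expect_equal(idv_to_mdv(c(0, 0.5, 0.5, 0)), c(0, 1, 0))
  set.seed(1)
  idv <- runif(16); idv <- idv / sum(idv)
  expect_equal(sum(idv_to_mdv(idv)), 1, tolerance = 1e-12)
  expect_equal(sum(idv_to_mdv(idv, natural_abundance = TRUE)), 1,
               tolerance = 1e-12)
})

test_that("tracer distributions encode position and purity", {
  idv <- tracer_idv(3, 3, 0.98)
  expect_equal(idv[1], 0.02)
  expect_equal(idv[5], 0.98) # carbon 3 set: index 1 + 4
  expect_equal(sum(idv), 1)
  idv_na <- tracer_idv(3, 3, 0.98, na_p = 0.0107)
  expect_equal(sum(idv_na), 1, tolerance = 1e-12)
  expect_lt(idv_na[1], 0.02)
})

test_that("unlabeled feed keeps every metabolite unlabeled", {
  run <- coarse_run_fx()
  sol <- solve_interval_idvs(toy_model_fx(), run$fluxes[40, ],
                             atom_maps_fx(),
                             inputs = list(lac = unlabeled_idv(3)))
  for (m in names(sol$idvs)) {
    expect_equal(sol$idvs[[m]][1], 1, tolerance = 1e-9)
    expect_equal(sum(sol$idvs[[m]]), 1, tolerance = 1e-9)
  }
})

test_that("tracer label passes through to pyruvate at purity", {
  run <- coarse_run_fx()
  sol <- solve_interval_idvs(toy_model_fx(), run$fluxes[40, ],
                             atom_maps_fx(), inputs = std_inputs_fx())
  pyr <- sol$idvs$pyr
  pos3 <- sum(pyr[bitwAnd(seq_along(pyr) - 1L, 4L) > 0])
  expect_equal(pos3, 0.98, tolerance = 1e-9)
  sums <- vapply(sol$idvs, sum, 1)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("label is conserved through the steady-state balance", {
  run <- coarse_run_fx()
  toy <- toy_model_fx()
  v <- run$fluxes[40, ]
  sol <- solve_interval_idvs(toy, v, atom_maps_fx(),
                             inputs = std_inputs_fx())
  enr <- function(m) idv_enrichment(sol$idvs[[m]])
  v_in <- -v[["EX_lac"]] * idv_enrichment(tracer_fx())
  aa <- toy_amino_acid_map()
  bio <- v[["BIOMASS"]]
  drains <- sum(vapply(seq_len(nrow(aa)), function(j)
    bio * aa$coeff[j] * enr(aa$precursor[j]), 1))
  extra <- bio * (3.0 * enr("accoa") + 1.2 * enr("g3p") + 0.25 * enr("c1"))
  v_out <- v[["EX_co2"]] * enr("co2") + v[["EX_ac"]] * enr("ace") +
    v[["EX_pyr"]] * enr("pyr") + drains + extra
  expect_equal(v_out, unname(v_in), tolerance = 1e-6)
})

test_that("zero exchange coefficients reproduce the irreversible solution", {
  run <- coarse_run_fx()
  base <- solve_interval_idvs(toy_model_fx(), run$fluxes[40, ],
                              atom_maps_fx(), inputs = std_inputs_fx())
  zero <- solve_interval_idvs(toy_model_fx(), run$fluxes[40, ],
                              atom_maps_fx(), inputs = std_inputs_fx(),
                              exch = c(ME2 = 0, SUCOAS = 0))
  expect_equal(zero$idvs, base$idvs, tolerance = 1e-12)
})

test_that("raising exch(ME2) mixes malate and pyruvate labeling", {
  run <- coarse_run_fx()
  dist <- vapply(c(0, 0.3, 0.6, 0.862), function(e) {
    sol <- solve_interval_idvs(toy_model_fx(), run$fluxes[40, ],
                               atom_maps_fx(), inputs = std_inputs_fx(),
                               exch = c(ME2 = e))
    sum(abs(idv_marginal(sol$idvs$mal, 3) - sol$idvs$pyr))
  }, 1)
  expect_true(all(diff(dist) < 0)) # distributions converge monotonically
})

test_that("protein labeling accumulates as a flux-weighted mean", {
  # two equal increments with opposite one-carbon labels average to half
  iv <- data.frame(dX = c(0.1, 0.1), v_bio = c(0.2, 0.2))
  series <- list(list(gly = c(1, 0, 0, 0)), list(gly = c(0, 0, 1, 0)))
  aa1 <- data.frame(aa = "Gly", precursor = "gly", coeff = 1.2)
  out <- accumulate_protein_labeling(series, iv, aa1)
  expect_equal(out$Gly, c(0.5, 0, 0.5, 0))
  # constant precursor labeling: integrated equals instantaneous
  series2 <- list(list(gly = c(0.3, 0.7, 0, 0)),
                  list(gly = c(0.3, 0.7, 0, 0)))
  iv2 <- data.frame(dX = c(0.1, 0.25), v_bio = c(0.2, 0.05))
  expect_equal(accumulate_protein_labeling(series2, iv2, aa1)$Gly,
               c(0.3, 0.7, 0, 0))
  expect_error(accumulate_protein_labeling(
    list(list(gly = NULL)), data.frame(dX = 1, v_bio = 1), aa1),
    "zero cumulative biomass")
})

test_that("the labeling simulation matches explicit re-summation", {
  run <- coarse_run_fx()
  sim <- simulate_labeling(run, atom_maps_fx(), labeling_experiment(),
                           exch = c(ME2 = 0.4), store_series = TRUE)
  fts <- data.frame(dX = run$intervals$dX,
                    v_bio = run$fluxes[, run$model$biomass])
  oracle <- accumulate_protein_labeling(sim$interval_idvs, fts)
  for (a in names(oracle))
    expect_equal(sim$idv_int[[a]], oracle[[a]], tolerance = 1e-12)
  # every reported vector is a probability vector
  all_vec <- c(unlist(sim$idv_int), unlist(sim$mdv))
  expect_true(all(all_vec >= -1e-12))
  sums <- c(vapply(sim$idv_int, sum, 1),
            unlist(lapply(sim$mdv, function(x) vapply(x, sum, 1))))
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("fit score weights squared errors by measurement error", {
  a <- list(Ala = c(0.1, 0.9), Gly = c(0.5, 0.5))
  expect_equal(score_fit(a, a), 0)
  b <- a; b$Ala[1] <- 0.12
  expect_equal(score_fit(a, b), 1, tolerance = 1e-10)
  b2 <- a; b2$Ala[1] <- 0.11; b2$Gly[1] <- 0.51
  expect_equal(score_fit(a, b2), 0.5, tolerance = 1e-10)
  expect_error(score_fit(a, list(Ala = c(0.1, 0.9))), "mismatched")
})
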