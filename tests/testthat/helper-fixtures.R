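# Shared fixtures, memoized so expensive objects are built once per run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

toy_model_fx <- function() memo("toy", build_toy_model())
atom_maps_fx <- function() memo("am", toy_atom_maps())

# noise-free hourly measurements from the published parameter set
clean_measurements_fx <- function() memo("meas", {
  ex <- default_experiment()
  generate_noisy_batch(ex$params, ex$init, ex$schedule, noise = 0, seed = 1)
})

# coarse dFBA run for unit tests (68 half-hour intervals)
coarse_run_fx <- function() memo("coarse_run", {
  run_dfba(toy_model_fx(), mr1_kinetics(), cfg = dfba_config(dt = 0.5))
})

# full-resolution run (408 five-minute intervals) for the acceptance suite
full_run_fx <- function() memo("full_run", {
  run_dfba(toy_model_fx(), mr1_kinetics(), cfg = dfba_config())
})

# tracer and standard input distributions for isotopomer tests
tracer_fx <- function() tracer_idv(3, 3, 0.98)
std_inputs_fx <- function() list(lac = tracer_fx(),
                                 ace = unlabeled_idv(2),
                                 pyr = unlabeled_idv(3),
                                 co2 = unlabeled_idv(1))

# five-reaction micro-network: A taken up (fixed), two parallel routes
# A -> B with a capacity cap, a free B waste sink, and a biomass drain on
# A + B. Two genuine degrees of freedom remain, so optima can be checked
# against a dense brute-force scan of the feasible polytope.
micro_model <- function() {
  mets <- c("A", "B")
  rxns <- c("EX_A", "R1", "R2", "R3", "BIO")
  S <- matrix(0, 2, 5, dimnames = list(mets, rxns))
  S["A", ] <- c(-1, -1, -1, 0, -0.6)
  S["B", ] <- c(0, 1, 1, -1, -0.4)
  stoich_model(mets, rxns, S,
               lb = c(-50, 0, 0, 0, 0),
               ub = c(0, 8, 8, 50, 50),
               biomass = "BIO",
               exchanges = list(lactate = "EX_A", acetate = "R3",
                                pyruvate = "R3", o2 = NULL, co2 = NULL))
}

# mean labeled-carbon count of an IDV
idv_enrichment <- function(idv) {
  n <- round(log2(length(idv)))
  bits <- vapply(seq_along(idv) - 1L, function(s)
    sum(as.integer(intToBits(s))[seq_len(n)]), 1L)
  sum(idv * bits)
}

# marginal IDV over the first k carbons
idv_marginal <- function(idv, k) {
  n <- round(log2(length(idv)))
  idx <- (seq_along(idv) - 1L) %% 2^k
  as.numeric(tapply(idv, idx, sum))
}
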