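test_that("toy network is structurally valid and feasible", {
  toy <- toy_model_fx()
  rep <- validate_model(toy)
  expect_true(rep$ok)
  expect_length(rep$failures, 0)
  # strictly positive growth on 10 mmol/g/h lactate (secretion-only
  # products)
  toy_sec <- set_bounds(toy, c("EX_ac", "EX_pyr"), lb = 0)
  sol <- solve_fba_max_growth(toy_sec, exchange_constraints(10))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$mu, 0.05)
  expect_lt(max(abs(toy$S %*% sol$flux)), 1e-9)
})

test_that("cutting citrate synthase and the glyoxylate route stops growth", {
  toy <- set_bounds(toy_model_fx(), c("EX_ac", "EX_pyr"), lb = 0)
  cut <- set_bounds(set_bounds(toy, "CS", ub = 0), "MALS", ub = 0)
  sol <- solve_fba_max_growth(cut, exchange_constraints(10))
  expect_lt(sol$mu, 1e-4)
})

test_that("growth on acetate requires the glyoxylate shunt", {
  toy <- toy_model_fx()
  ec <- exchange_constraints(0, -10, 0)
  mu_full <- solve_fba_max_growth(toy, ec)$mu
  mu_cut <- solve_fba_max_growth(set_bounds(toy, "ICL", ub = 0), ec)$mu
  expect_gt(mu_full, 0.05)
  expect_lt(mu_cut, 1e-4)
})

test_that("SBML round-trips bounds, stoichiometry and annotations", {
  toy <- toy_model_fx()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy, f)
  m2 <- read_sbml(f)
  expect_equal(length(m2$mets), length(toy$mets))
  expect_equal(length(m2$rxns), length(toy$rxns))
  expect_equal(m2$S[toy$mets, toy$rxns], toy$S, tolerance = 1e-12)
  expect_equal(m2$lb[toy$rxns], toy$lb, tolerance = 1e-12)
  expect_equal(m2$ub[toy$rxns], toy$ub, tolerance = 1e-12)
  expect_equal(m2$biomass, "BIOMASS")
  expect_equal(m2$exchanges$lactate, "EX_lac")
  expect_equal(m2$exchanges$acetate, "EX_ac")
})

test_that("crossed bounds are a validation error naming the reaction", {
  toy <- toy_model_fx()
  f <- withr::local_tempfile(fileext = ".xml")
  bad <- toy
  bad$lb["PDH"] <- 5
  bad$ub["PDH"] <- -5
  # write without the constructor check, then read back
  bad2 <- unclass(bad)
  class(bad2) <- "stoich_model"
  write_sbml(bad2, f)
  expect_error(read_sbml(f), "PDH")
})

test_that("validation reports missing biomass and orphan metabolites", {
  toy <- toy_model_fx()
  m <- toy
  m$biomass <- "NOT_THERE"
  rep <- validate_model(m)
  expect_true("biomass_missing" %in%
                vapply(rep$failures, `[[`, "", "code"))
  m2 <- toy
  m2$S <- rbind(m2$S, orphan = 0)
  m2$mets <- c(m2$mets, "orphan")
  rep2 <- validate_model(m2)
  expect_true("orphan_metabolite" %in%
                vapply(rep2$warnings, `[[`, "", "code"))
})

test_that("malformed SBML and missing files give clear errors", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model</sbml>", f)
  expect_error(read_sbml(f), "malformed")
  expect_error(read_sbml(file.path(tempdir(), "nope.xml")), "not found")
})

test_that("L2 COBRA-dialect bounds are honoured", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="lac" compartment="c"/>',
    '<species id="b" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="EX_lac" reversible="true">',
    '<listOfReactants><speciesReference species="lac"/></listOfReactants>',
    '<kineticLaw><math/>',
    '<listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-12.5"/>',
    '<parameter id="UPPER_BOUND" value="4"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="EX_ac" reversible="true">',
    '<listOfReactants><speciesReference species="lac"/></listOfReactants>',
    '</reaction>',
    '<reaction id="EX_pyr" reversible="false">',
    '<listOfReactants><speciesReference species="lac"/></listOfReactants>',
    '</reaction>',
    '<reaction id="biomass_rxn" reversible="false">',
    '<listOfReactants><speciesReference species="lac"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), f)
  m <- read_sbml(f)
  expect_equal(unname(m$lb["EX_lac"]), -12.5)
  expect_equal(unname(m$ub["EX_lac"]), 4)
  expect_equal(unname(m$lb["EX_ac"]), -1000) # reversible default
  expect_equal(unname(m$lb["EX_pyr"]), 0)    # irreversible default
  expect_equal(m$biomass, "biomass_rxn")
})
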