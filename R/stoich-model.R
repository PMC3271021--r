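#' Construct a stoichiometric model
#'
#' Container for the flux-balance layers: metabolite and reaction
#' identifiers, the stoichiometric matrix S (metabolites x reactions), flux
#' bounds (mmol/g DCW/h; the biomass reaction in 1/h), the biomass reaction
#' id and the exchange-reaction map for lactate, acetate, pyruvate, O2 and
#' CO2.
#'
#' Sign convention, used everywhere in the package: exchange flux > 0 means
#' secretion, < 0 means uptake; uptake capacity is expressed as a negative
#' lower bound.
#'
#' @param mets character metabolite ids.
#' @param rxns character reaction ids.
#' @param S numeric matrix, `length(mets)` x `length(rxns)`.
#' @param lb,ub numeric flux bounds per reaction.
#' @param biomass id of the biomass reaction.
#' @param exchanges named list/character mapping roles
#'   (`lactate`, `acetate`, `pyruvate`, `o2`, `co2`) to reaction ids.
#' @param check validate invariants (default TRUE).
#' @return an object of class `stoich_model`.
#' @export
stoich_model <- function(mets, rxns, S, lb, ub, biomass, exchanges,
                         check = TRUE) {
  S <- as.matrix(S)
  dimnames(S) <- list(mets, rxns)
  names(lb) <- names(ub) <- rxns
  model <- structure(
    list(mets = mets, rxns = rxns, S = S, lb = lb, ub = ub,
         biomass = biomass, exchanges = as.list(exchanges),
         reversible = lb < 0),
    class = "stoich_model")
  if (check) {
    rep <- validate_model(model)
    if (length(rep$failures))
      stop("invalid model: ", paste(vapply(rep$failures, `[[`, "", "code"),
                                    collapse = ", "))
  }
  model
}

#' Validate a stoichiometric model
#'
#' Checks structural invariants (dimensions, bound ordering, resolvable
#' biomass and exchange reactions) and scans for dead-end metabolites
#' (orphan all-zero rows, or metabolites that are only produced or only
#' consumed by irreversible reactions). Failures and warnings are returned
#' as a machine-readable report, not raised.
#'
#' @param model a `stoich_model`.
#' @return list with elements `failures` and `warnings`, each a list of
#'   `list(code=, detail=)` records, and `ok` (no failures).
#' @export
validate_model <- function(model) {
  failures <- list()
  warnings <- list()
  fail <- function(code, detail = "")
    failures[[length(failures) + 1L]] <<- list(code = code, detail = detail)
  warn <- function(code, detail = "")
    warnings[[length(warnings) + 1L]] <<- list(code = code, detail = detail)

  if (!identical(dim(model$S), c(length(model$mets), length(model$rxns))))
    fail("dim_mismatch", "S inconsistent with id lists")
  if (any(model$lb > model$ub)) {
    bad <- model$rxns[model$lb > model$ub]
    fail("bounds_crossed", paste(bad, collapse = ","))
  }
  if (is.null(model$biomass) || !model$biomass %in% model$rxns)
    fail("biomass_missing", as.character(model$biomass))
  for (role in c("lactate", "acetate", "pyruvate")) {
    id <- model$exchanges[[role]]
    if (is.null(id) || !id %in% model$rxns)
      fail("exchange_missing", role)
  }
  orphan <- rowSums(model$S != 0) == 0
  if (any(orphan)) warn("orphan_metabolite",
                        paste(model$mets[orphan], collapse = ","))
  list(failures = failures, warnings = warnings, ok = !length(failures))
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("Stoichiometric model: %d metabolites x %d reactions\n",
              length(x$mets), length(x$rxns)))
  cat("  biomass:", x$biomass, " exchanges:",
      paste(names(x$exchanges), unlist(x$exchanges), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Set flux bounds on a model
#'
#' @param model a `stoich_model`.
#' @param rxn reaction id(s).
#' @param lb,ub new bounds (recycled); `NULL` leaves a side unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  miss <- setdiff(rxn, model$rxns)
  if (length(miss)) stop("unknown reaction(s): ", paste(miss, collapse = ", "))
  if (!is.null(lb)) model$lb[rxn] <- lb
  if (!is.null(ub)) model$ub[rxn] <- ub
  if (any(model$lb[rxn] > model$ub[rxn]))
    stop("lb > ub after update for: ",
         paste(rxn[model$lb[rxn] > model$ub[rxn]], collapse = ", "))
  model
}

#' Desk-scale central-carbon network
#'
#' A 28-reaction, 20-metabolite toy model of aerobic lactate metabolism:
#' lactate to pyruvate to acetyl-CoA, acetate and pyruvate exchanges
#' (overflow and reuse), the oxidative TCA cycle, the glyoxylate shunt
#' (ICL/MALS), malic enzyme (ME2) and pyruvate carboxylase anaplerosis, a
#' lumped gluconeogenesis precursor drain, serine/glycine/C1 biosynthesis
#' with a C1 oxidation valve (formate-dehydrogenase-like), respiration with
#' NADH/ATP pseudo-metabolites, a maintenance ATPase and a biomass reaction
#' draining amino-acid precursors (pyruvate, acetyl-CoA, oxaloacetate,
#' 2-oxoglutarate, serine, glycine, C1, 3-phosphoglycerate) plus ATP.
#'
#' Energetics are deliberately Shewanella-like: the coupled NADH oxidase
#' (`OXPHOS`) carries a low aerobic P/O of 1, an uncoupled NADH oxidase
#' (`NOX`, energy spilling) lets the cell re-oxidize NADH without ATP
#' formation, and the biomass reaction carries a high lumped growth-
#' associated ATP demand (220 mmol/g DCW). Together these make fast growth
#' flux-expensive, so the dual-objective growth rate declines appreciably
#' as the flux-minimization weight rises - the regime the bi-level weight
#' search operates in.
#'
#' By construction the model grows on lactate while secreting acetate and
#' pyruvate, and growth on acetate alone requires glyoxylate-shunt flux.
#' Biomass precursor coefficients total ~42 mmol C per g DCW.
#'
#' @return a `stoich_model`.
#' @export
#' @examples
#' toy <- build_toy_model()
#' toy
build_toy_model <- function() {
  mets <- c("lac", "pyr", "ace", "accoa", "co2", "o2", "cit", "akg",
            "succoa", "suc", "fum", "mal", "glx", "oaa", "g3p", "ser",
            "gly", "c1", "nadh", "atp")
  # reaction list: list(id, stoich (named), lb, ub)
  rx <- list(
    list("EX_lac",  c(lac = -1),                         -1000, 0),
    list("EX_pyr",  c(pyr = -1),                         -1000, 1000),
    list("EX_ac",   c(ace = -1),                         -1000, 1000),
    list("EX_o2",   c(o2 = -1),                          -1000, 0),
    list("EX_co2",  c(co2 = -1),                         -1000, 1000),
    list("LDH",     c(lac = -1, pyr = 1, nadh = 1),          0, 1000),
    list("PDH",     c(pyr = -1, accoa = 1, co2 = 1, nadh = 1), 0, 1000),
    list("ACS",     c(accoa = -1, ace = 1),              -1000, 1000),
    list("CS",      c(oaa = -1, accoa = -1, cit = 1),        0, 1000),
    list("ICDH",    c(cit = -1, akg = 1, co2 = 1, nadh = 1), 0, 1000),
    list("AKGDH",   c(akg = -1, succoa = 1, co2 = 1, nadh = 1), 0, 1000),
    list("SUCOAS",  c(succoa = -1, suc = 1, atp = 1),    -1000, 1000),
    list("SDH",     c(suc = -1, fum = 1, nadh = 1),          0, 1000),
    list("FUM",     c(fum = -1, mal = 1),                -1000, 1000),
    list("MDH",     c(mal = -1, oaa = 1, nadh = 1),          0, 1000),
    list("ICL",     c(cit = -1, glx = 1, suc = 1),           0, 1000),
    list("MALS",    c(glx = -1, accoa = -1, mal = 1),        0, 1000),
    list("ME2",     c(mal = -1, pyr = 1, co2 = 1, nadh = 1), 0, 1000),
    list("PYC",     c(pyr = -1, co2 = -1, atp = -1, oaa = 1), 0, 1000),
    list("GNG",     c(oaa = -1, atp = -1, g3p = 1, co2 = 1), 0, 1000),
    list("SERS",    c(g3p = -1, ser = 1),                    0, 1000),
    list("GHMT",    c(ser = -1, gly = 1, c1 = 1),        -1000, 1000),
    list("GLYCL",   c(gly = -1, co2 = 1, c1 = 1, nadh = 1),  0, 1000),
    list("C1OX",    c(c1 = -1, co2 = 1, nadh = 1),           0, 1000),
    list("OXPHOS",  c(nadh = -1, o2 = -0.5, atp = 1),        0, 1000),
    list("NOX",     c(nadh = -1, o2 = -0.5),                 0, 1000),
    list("ATPM",    c(atp = -1),                             0, 1000),
    list("BIOMASS", c(pyr = -2.5, accoa = -3.0, oaa = -2.0, akg = -2.2,
                      ser = -1.0, gly = -1.2, c1 = -0.25, g3p = -1.2,
                      atp = -220),                           0, 1000)
  )
  rxns <- vapply(rx, `[[`, "", 1)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in rx) S[names(r[[2]]), r[[1]]] <- r[[2]]
  stoich_model(mets, rxns, S,
               lb = vapply(rx, `[[`, 0, 3), ub = vapply(rx, `[[`, 0, 4),
               biomass = "BIOMASS",
               exchanges = list(lactate = "EX_lac", acetate = "EX_ac",
                                pyruvate = "EX_pyr", o2 = "EX_o2",
                                co2 = "EX_co2"))
}
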