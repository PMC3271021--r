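#' Read a stoichiometric model from SBML
#'
#' Accepts SBML Level 3 with the `fbc` flux-bounds package, and Level 2
#' files in the COBRA dialect (bounds as `LOWER_BOUND`/`UPPER_BOUND`
#' kinetic-law parameters). Missing bounds default to `[0, 1000]` for
#' irreversible and `[-1000, 1000]` for reversible reactions. Boundary
#' species (`boundaryCondition="true"`) are excluded from the balance.
#'
#' Exchange reactions for the five roles (lactate, acetate, pyruvate, O2,
#' CO2) and the biomass reaction are resolved from id patterns; the
#' defaults cover common conventions (`EX_*` prefixes, `biomass`/`growth`
#' substrings) and can be overridden for models with other id schemes.
#'
#' @param path SBML file.
#' @param exchange_patterns named character vector of regular expressions
#'   (case-insensitive, matched against reaction ids of exchange reactions)
#'   for roles `lactate`, `acetate`, `pyruvate`, `o2`, `co2`.
#' @param biomass_pattern regular expression locating the biomass reaction
#'   (the fbc active objective, when present, takes precedence).
#' @return a `stoich_model`.
#' @export
read_sbml <- function(path,
                      exchange_patterns = c(
                        lactate = "^(R_)?EX_.*lac|^lac", acetate = "^(R_)?EX_ac(e|t)?(_|$)|^ac",
                        pyruvate = "^(R_)?EX_pyr|^pyr", o2 = "o2", co2 = "co2"),
                      biomass_pattern = "biomass|growth") {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML: ", conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(model_node)) stop("malformed SBML: no <model> element")

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_bnd <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- sp_id[!sp_bnd]

  # global parameters (fbc bound references)
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(rxns)) stop("malformed SBML: duplicate reaction ids")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- stats::setNames(numeric(length(rxns)), rxns)
  for (j in seq_along(rxns)) {
    node <- rx[[j]]
    rev <- !(xml2::xml_attr(node, "reversible") %in% "false")
    for (side in c(-1, 1)) {
      refs <- xml2::xml_find_all(node, if (side < 0)
        "./listOfReactants/speciesReference" else
        "./listOfProducts/speciesReference")
      for (ref in refs) {
        s <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (s %in% mets) S[s, j] <- S[s, j] + side * st
      }
    }
    blo <- xml2::xml_attr(node, "lowerFluxBound")
    bup <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(blo) || !is.na(bup)) { # L3 fbc
      lb[j] <- if (!is.na(blo)) pars[[blo]] else -1000
      ub[j] <- if (!is.na(bup)) pars[[bup]] else 1000
    } else {
      kl <- xml2::xml_find_all(node,
        ".//kineticLaw//parameter | .//kineticLaw//localParameter")
      kid <- toupper(xml2::xml_attr(kl, "id"))
      kval <- as.numeric(xml2::xml_attr(kl, "value"))
      lo_i <- match("LOWER_BOUND", kid); up_i <- match("UPPER_BOUND", kid)
      lb[j] <- if (!is.na(lo_i)) kval[lo_i] else if (rev) -1000 else 0
      ub[j] <- if (!is.na(up_i)) kval[up_i] else 1000
    }
  }
  bad <- rxns[lb > ub]
  if (length(bad))
    stop("validation error: lb > ub for reaction(s): ",
         paste(bad, collapse = ", "))

  # exchange reactions: single-metabolite columns, or boundary-species sinks
  n_net <- colSums(S != 0)
  is_ex <- n_net == 1 | grepl("^(EX_|R_EX_)", rxns)
  resolve <- function(pattern, pool) {
    hit <- pool[grepl(pattern, pool, ignore.case = TRUE)]
    if (length(hit)) hit[1] else NULL
  }
  exchanges <- lapply(exchange_patterns, resolve, pool = rxns[is_ex])
  missing_roles <- names(exchanges)[vapply(exchanges, is.null, TRUE)]
  if (any(c("lactate", "acetate", "pyruvate") %in% missing_roles))
    stop("configuration error: cannot resolve exchange reaction(s) for: ",
         paste(missing_roles, collapse = ", "),
         " (adjust exchange_patterns)")

  biomass <- NULL
  obj <- xml2::xml_find_first(doc, ".//fluxObjective")
  if (!is.na(obj)) biomass <- xml2::xml_attr(obj, "reaction")
  if (is.null(biomass) || !biomass %in% rxns)
    biomass <- resolve(biomass_pattern, rxns)
  if (is.null(biomass))
    stop("configuration error: cannot resolve the biomass reaction")

  stoich_model(mets, rxns, S, lb, ub, biomass, exchanges)
}

#' Write a stoichiometric model as SBML Level 3 + fbc
#'
#' Emits SBML L3v1 with the fbc-v2 package: species, reactions with
#' stoichiometry, flux bounds as shared global parameters, and the biomass
#' reaction as the active maximization objective. Round-trips through
#' [read_sbml()] preserving counts, bounds and stoichiometry.
#'
#' @param model a `stoich_model`.
#' @param path output file.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  bounds <- sort(unique(c(model$lb, model$ub)))
  bid <- function(v) sprintf("fb_%s", gsub("[^0-9A-Za-z]", "_",
                                           formatC(v, format = "g")))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="dynafba_model" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" compartment="c" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'), esc(model$mets)),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf(paste0('      <parameter id="%s" value="%.12g" ',
                   'constant="true"/>'), bid(bounds), bounds),
    '    </listOfParameters>')
  rx_lines <- unlist(lapply(seq_along(model$rxns), function(j) {
    id <- model$rxns[j]
    col <- model$S[, j]
    reac <- names(col)[col < 0]; prod <- names(col)[col > 0]
    out <- sprintf(paste0('      <reaction id="%s" reversible="%s" ',
                          'fast="false" fbc:lowerFluxBound="%s" ',
                          'fbc:upperFluxBound="%s">'),
                   esc(id), tolower(model$lb[j] < 0),
                   bid(model$lb[j]), bid(model$ub[j]))
    if (length(reac))
      out <- c(out, '        <listOfReactants>',
               sprintf(paste0('          <speciesReference species="%s" ',
                              'stoichiometry="%.12g" constant="true"/>'),
                       esc(reac), -col[reac]),
               '        </listOfReactants>')
    if (length(prod))
      out <- c(out, '        <listOfProducts>',
               sprintf(paste0('          <speciesReference species="%s" ',
                              'stoichiometry="%.12g" constant="true"/>'),
                       esc(prod), col[prod]),
               '        </listOfProducts>')
    c(out, '      </reaction>')
  }))
  lines <- c(lines,
    '    <listOfReactions>', rx_lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                   'fbc:coefficient="1"/>'), esc(model$biomass)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Model summary as JSON
#'
#' @param model a `stoich_model`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
model_summary_json <- function(model, path = NULL) {
  s <- list(n_metabolites = length(model$mets),
            n_reactions = length(model$rxns),
            biomass = model$biomass,
            exchanges = model$exchanges,
            n_reversible = sum(model$lb < 0))
  if (is.null(path)) return(jsonlite::toJSON(s, auto_unbox = TRUE))
  jsonlite::write_json(s, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
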