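#' Kinetic parameters of the multi-substrate Monod batch model
#'
#' Constructs and validates the 14-parameter set of the lag-phase Monod model
#' for batch growth on lactate with overflow to, and reuse of, pyruvate and
#' acetate.
#'
#' The parameters are, in order: maximal specific growth rates on lactate,
#' acetate and pyruvate (`mu_max_L`, `mu_max_A`, `mu_max_P`, 1/h); apparent
#' biomass yields (`Y_XL`, `Y_XA`, `Y_XP`, g DCW/mol substrate); Monod
#' saturation constants (`Ks_l`, `Ks_a`, `Ks_p`, mM); overflow rate constants
#' for acetate-from-lactate, pyruvate-from-lactate and acetate-from-pyruvate
#' production (`k_al`, `k_pl`, `k_ap`, L/(h g DCW)); the endogenous
#' metabolism rate constant `k_e` (1/h); and the lag time `t_L` (h).
#'
#' @param mu_max_L,mu_max_A,mu_max_P maximal specific growth rates (1/h).
#' @param Y_XL,Y_XA,Y_XP apparent biomass yields (g DCW/mol).
#' @param Ks_l,Ks_a,Ks_p Monod saturation constants (mM).
#' @param k_al,k_pl,k_ap overflow rate constants (L/(h g DCW)).
#' @param k_e endogenous metabolism rate constant (1/h).
#' @param t_L lag time (h).
#' @return An object of class `monod_params`: a named numeric vector of
#'   length 14.
#' @seealso [mr1_kinetics()] for the published *Shewanella oneidensis* MR-1
#'   estimates, [fit_monod()] to estimate the set from data.
#' @export
#' @examples
#' p <- mr1_kinetics()
#' p["mu_max_L"]
monod_params <- function(mu_max_L, mu_max_A, mu_max_P,
                         Y_XL, Y_XA, Y_XP,
                         Ks_l, Ks_a, Ks_p,
                         k_al, k_pl, k_ap,
                         k_e, t_L) {
  p <- c(mu_max_L = mu_max_L, mu_max_A = mu_max_A, mu_max_P = mu_max_P,
         Y_XL = Y_XL, Y_XA = Y_XA, Y_XP = Y_XP,
         Ks_l = Ks_l, Ks_a = Ks_a, Ks_p = Ks_p,
         k_al = k_al, k_pl = k_pl, k_ap = k_ap,
         k_e = k_e, t_L = t_L)
  validate_monod_params(p)
  class(p) <- "monod_params"
  p
}

#' @rdname monod_params
#' @param x a numeric vector with the 14 parameter names above (any order).
#' @export
as_monod_params <- function(x) {
  x <- unlist(x)
  miss <- setdiff(monod_param_names(), names(x))
  if (length(miss))
    stop("missing kinetic parameters: ", paste(miss, collapse = ", "))
  p <- x[monod_param_names()]
  validate_monod_params(p)
  class(p) <- "monod_params"
  p
}

monod_param_names <- function() {
  c("mu_max_L", "mu_max_A", "mu_max_P", "Y_XL", "Y_XA", "Y_XP",
    "Ks_l", "Ks_a", "Ks_p", "k_al", "k_pl", "k_ap", "k_e", "t_L")
}

validate_monod_params <- function(p, horizon = NULL) {
  if (any(!is.finite(p))) stop("kinetic parameters must be finite")
  if (any(p < 0)) stop("kinetic parameters must be non-negative: ",
                       paste(names(p)[p < 0], collapse = ", "))
  if (any(p[c("Y_XL", "Y_XA", "Y_XP")] <= 0))
    stop("biomass yields must be strictly positive")
  if (!is.null(horizon) && p[["t_L"]] > horizon)
    stop("lag time t_L lies beyond the observation horizon")
  invisible(p)
}

#' Published Monod parameter estimates for Shewanella oneidensis MR-1
#'
#' Returns the reported point estimates of the 14 Monod-model constants for
#' aerobic batch growth of *S. oneidensis* MR-1 on ~30 mM lactate: preferential
#' lactate use (`mu_max_L` = 0.57/h) with overflow to pyruvate and acetate and
#' their later reuse, a 7.1-h lag, and a small endogenous decay.
#'
#' @return A `monod_params` vector.
#' @export
mr1_kinetics <- function() {
  monod_params(
    mu_max_L = 0.57, mu_max_A = 0.13, mu_max_P = 0.14,
    Y_XL = 17.0, Y_XA = 11.1, Y_XP = 16.7,
    Ks_l = 19.4, Ks_a = 10.1, Ks_p = 19.4,
    k_al = 0.71, k_pl = 0.45, k_ap = 0.94,
    k_e = 0.013, t_L = 7.10
  )
}

#' @export
print.monod_params <- function(x, ...) {
  cat("Multi-substrate Monod kinetic parameters\n")
  units <- c(rep("1/h", 3), rep("g DCW/mol", 3), rep("mM", 3),
             rep("L/(h gDCW)", 3), "1/h", "h")
  df <- data.frame(value = as.numeric(x), unit = units,
                   row.names = names(unclass(x)))
  print(df, ...)
  invisible(x)
}

#' Read and write kinetic parameters as JSON
#'
#' The on-disk format is a JSON object with a `parameters` block keyed by the
#' 14 parameter symbols and a `units` block documenting their units.
#'
#' @param path file path.
#' @return `read_params_json` returns a `monod_params` vector;
#'   `write_params_json` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  src <- if (!is.null(doc$parameters)) doc$parameters else doc
  as_monod_params(src)
}

#' @rdname read_params_json
#' @param p a `monod_params` vector.
#' @param sd optional named vector of parameter standard deviations
#'   (e.g. from [bootstrap_monod()]), stored alongside the point estimates.
#' @export
write_params_json <- function(p, path, sd = NULL) {
  p <- as_monod_params(p)
  units <- list(
    mu_max = "1/h", yields = "g DCW/mol substrate", Ks = "mM",
    overflow_k = "L/(h g DCW)", k_e = "1/h", t_L = "h"
  )
  doc <- list(parameters = as.list(unclass(p)), units = units)
  if (!is.null(sd)) doc$sd <- as.list(sd)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
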