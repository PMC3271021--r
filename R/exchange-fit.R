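#' Fit pathway exchange coefficients to measured amino-acid labeling
#'
#' Estimates the reversibility (exchange) coefficients of designated
#' pathways by bound-constrained minimization of the sigma-weighted fit
#' score between simulated and measured amino-acid mass distributions at
#' the harvest times. One coefficient is optimized by golden-section
#' search, several jointly by `nlminb` with numerical gradients; both are
#' deterministic for a fixed start. Asymptotic confidence intervals come
#' from the local curvature (numerical Hessian) of the objective; a flat
#' objective (non-identifiable pathway) yields the full \[0, 1) interval
#' with a warning.
#'
#' @param run a `dfba_run` supplying the flux series.
#' @param am an `atom_map`.
#' @param experiment a [labeling_experiment].
#' @param exp_mdvs measured MDVs: a named list (per harvest time, matching
#'   `format(experiment$harvest_times)`) of named lists of per-amino-acid
#'   MDVs — the shape produced in the `mdv` field of [simulate_labeling()].
#' @param pathways character vector of reaction ids to fit (subset of the
#'   designated reversible set).
#' @param sigma GC-MS measurement standard deviation (default 0.02).
#' @param start initial coefficient value(s).
#' @param upper upper bound, strictly below 1.
#' @param aa_map amino-acid precursor table.
#' @return an `exchange_fit` object: `coefficients` (named), `ci` (2-column
#'   matrix), `objective`, `n_obs`, `convergence`.
#' @export
fit_exchange_coefficients <- function(run, am, experiment, exp_mdvs,
                                      pathways = "ME2", sigma = 0.02,
                                      start = 0.5, upper = 0.995,
                                      aa_map = toy_amino_acid_map()) {
  stopifnot(length(pathways) >= 1, all(start >= 0), all(start < 1))
  start <- rep_len(start, length(pathways))
  times <- intersect(names(exp_mdvs),
                     format(sort(experiment$harvest_times)))
  if (!length(times)) stop("no harvest times in common with exp_mdvs")

  obj <- function(theta) {
    exch <- stats::setNames(theta, pathways)
    sim <- simulate_labeling(run, am, experiment, exch = exch,
                             aa_map = aa_map)
    total <- 0
    for (tn in times)
      total <- total + score_fit(sim$mdv[[tn]], exp_mdvs[[tn]],
                                 sigma = sigma)
    total
  }
  if (length(pathways) == 1) {
    opt <- stats::optimize(obj, c(0, upper), tol = 1e-5)
    theta <- opt$minimum; fval <- opt$objective
    conv <- TRUE
  } else {
    opt <- stats::nlminb(start, obj, lower = rep(0, length(pathways)),
                         upper = rep(upper, length(pathways)),
                         control = list(rel.tol = 1e-9))
    theta <- opt$par; fval <- opt$objective
    conv <- opt$convergence == 0
  }
  names(theta) <- pathways

  n_obs <- sum(vapply(times, function(tn)
    sum(lengths(exp_mdvs[[tn]])), 1L))
  dof <- max(1L, n_obs - length(pathways))
  s2 <- fval / dof
  h <- 1e-2
  ci <- matrix(NA_real_, length(pathways), 2,
               dimnames = list(pathways, c("lower", "upper")))
  flat <- character(0)
  for (j in seq_along(pathways)) {
    tp <- tm <- theta
    tp[j] <- min(theta[j] + h, upper); tm[j] <- max(theta[j] - h, 0)
    hj <- (tp[j] - theta[j] + theta[j] - tm[j]) / 2
    d2 <- (obj(tp) - 2 * fval + obj(tm)) / hj^2
    if (!is.finite(d2) || d2 < 1e-8) {
      ci[j, ] <- c(0, 1)
      flat <- c(flat, pathways[j])
    } else {
      half <- stats::qt(0.975, dof) * sqrt(2 * s2 / d2)
      ci[j, ] <- c(max(0, theta[j] - half), min(1, theta[j] + half))
    }
  }
  if (length(flat))
    warning("flat objective, coefficient(s) not identifiable: ",
            paste(flat, collapse = ", "))
  structure(list(coefficients = theta, ci = ci, objective = fval,
                 n_obs = n_obs, convergence = conv),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Exchange-coefficient fit (weighted SSR =",
      format(x$objective, digits = 4), ")\n")
  df <- data.frame(exch = x$coefficients,
                   ci_lower = x$ci[, 1], ci_upper = x$ci[, 2])
  print(df, ...)
  invisible(x)
}

#' @export
coef.exchange_fit <- function(object, ...) object$coefficients

#' @export
confint.exchange_fit <- function(object, parm, level = 0.95, ...) {
  object$ci
}
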