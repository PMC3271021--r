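#' Exchange-flux constraints for one pseudo-steady-state interval
#'
#' Specific exchange fluxes (mmol/g DCW/h) derived from the kinetic model:
#' lactate inflow (non-negative uptake magnitude), and signed acetate and
#' pyruvate flows (positive = secretion, negative = uptake, matching the
#' package-wide exchange sign convention).
#'
#' @param v_lac_inflow lactate uptake magnitude (>= 0).
#' @param v_act_flow,v_pyr_flow signed acetate/pyruvate exchange fluxes.
#'   `NA` leaves that exchange free within its model bounds instead of
#'   fixing it.
#' @return an `exchange_constraints` object.
#' @export
exchange_constraints <- function(v_lac_inflow, v_act_flow = NA,
                                 v_pyr_flow = NA) {
  v <- c(v_lac_inflow = v_lac_inflow, v_act_flow = v_act_flow,
         v_pyr_flow = v_pyr_flow)
  if (any(is.infinite(v) | is.nan(v)))
    stop("exchange constraints must be finite or NA")
  if (!is.na(v[["v_lac_inflow"]]) && v[["v_lac_inflow"]] < 0)
    stop("v_lac_inflow must be non-negative")
  structure(as.list(v), class = "exchange_constraints")
}

# Assemble the equality system S v = 0 plus the three Monod-derived
# exchanges fixed to their values, then eliminate the equalities through a
# null-space (SVD) reduction: v = v_p + N z with orthonormal N. The box
# bounds become linear inequalities on the reduced coordinate z, leaving a
# small dense QP that the active-set solver handles robustly (the full-size
# problem, with ~n-3 equality rows, is too degenerate for it).
fba_system <- function(model, ec) {
  n <- length(model$rxns)
  fixed <- c(model$exchanges$lactate, model$exchanges$acetate,
             model$exchanges$pyruvate)
  vals <- c(-ec$v_lac_inflow, ec$v_act_flow, ec$v_pyr_flow)
  fixed <- fixed[!is.na(vals)]; vals <- vals[!is.na(vals)]
  E <- matrix(0, length(fixed), n, dimnames = list(NULL, model$rxns))
  E[cbind(seq_along(fixed), match(fixed, model$rxns))] <- 1
  lb <- model$lb; ub <- model$ub
  lb[fixed] <- -Inf; ub[fixed] <- Inf
  Aeq <- rbind(unname(model$S), E)
  beq <- c(rep(0, nrow(model$S)), vals)

  sv <- svd(Aeq, nu = nrow(Aeq), nv = n)
  tol <- max(dim(Aeq)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  v_p <- sv$v[, seq_len(r), drop = FALSE] %*%
    (crossprod(sv$u[, seq_len(r), drop = FALSE], beq) / sv$d[seq_len(r)])
  eq_ok <- max(abs(Aeq %*% v_p - beq)) < 1e-7 * max(1, max(abs(beq)))
  N <- if (r < n) sv$v[, (r + 1):n, drop = FALSE] else
    matrix(0, n, 0)

  # box bounds as inequalities A z <= b (finite rows only)
  A <- rbind(N, -N)
  b <- c(ub - v_p, v_p - lb)
  keep <- is.finite(b)
  list(v_p = drop(v_p), N = N, k = ncol(N), A = A[keep, , drop = FALSE],
       b = b[keep], eq_ok = eq_ok, n = n,
       i_bio = match(model$biomass, model$rxns))
}

# Goldfarb-Idnani QP in the reduced coordinate: maximize d'v - w ||v||^2
# over v = v_p + N z subject to the box inequalities (optionally extra rows
# A_x z <= b_x). Returns the full-space flux vector, or NULL when
# infeasible.
# The inequalities are relaxed by `feas_tol` before solving: flux polytopes
# routinely have faces of zero width (an irreversible reaction pinned at
# zero by the balances), and the active-set solver mistakes that degeneracy
# for inconsistency. Solutions are therefore feasible to within feas_tol.
qp_point <- function(sys, w, d, A_extra = NULL, b_extra = NULL,
                     feas_tol = getOption("dynafba.feas_tol", 1e-9)) {
  if (!sys$eq_ok) return(NULL)
  A <- sys$A; b <- sys$b
  if (!is.null(A_extra)) { A <- rbind(A, A_extra); b <- c(b, b_extra) }
  if (sys$k == 0) # fully determined by the equalities
    return(if (all(b >= -feas_tol)) sys$v_p else NULL)
  dz <- drop(2 * w * crossprod(sys$N, sys$v_p) - crossprod(sys$N, d))
  ans <- tryCatch(
    pracma::quadprog(diag(2 * w, sys$k), dz, A = A, b = b + feas_tol),
    error = function(e) e, warning = function(w2) w2)
  if (inherits(ans, "condition")) {
    if (!grepl("inconsistent|no solution", conditionMessage(ans)))
      message("QP solver: ", conditionMessage(ans))
    # retry once at a relaxed tolerance before declaring infeasibility
    ans <- tryCatch(
      pracma::quadprog(diag(2 * w + 1e-12, sys$k), dz, A = A,
                       b = b + 1e3 * feas_tol),
      error = function(e) NULL, warning = function(w2) NULL)
    if (is.null(ans)) return(NULL)
  }
  drop(sys$v_p + sys$N %*% ans$xmin)
}

flux_solution <- function(model, v, w, status) {
  if (status != "optimal")
    return(structure(list(flux = NULL, mu = NA_real_, sum_sq = NA_real_,
                          status = status, w = w), class = "flux_solution"))
  names(v) <- model$rxns
  structure(list(flux = v, mu = v[[model$biomass]], sum_sq = sum(v^2),
                 status = "optimal", w = w), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  if (x$status != "optimal") {
    cat("Flux solution:", x$status, "\n")
  } else {
    cat(sprintf("Flux solution: mu = %.6g 1/h, sum(v^2) = %.6g, w = %g\n",
                x$mu, x$sum_sq, x$w))
  }
  invisible(x)
}

#' Maximum-growth flux balance analysis
#'
#' Solves the pseudo-steady-state linear program max biomass flux subject to
#' S v = 0, the flux bounds, and the three kinetically derived exchange
#' fluxes imposed as equalities. The maximum is located by bisection on the
#' growth rate, using strictly convex minimum-norm quadratic feasibility
#' probes (the active-set solver signals infeasibility exactly); the
#' returned flux vector is the minimum-norm optimal solution, one valid
#' vertex of the (possibly degenerate) optimal face.
#'
#' @param model a `stoich_model`.
#' @param ec an [exchange_constraints] object.
#' @param tol bisection tolerance on the growth rate (1/h).
#' @return a `flux_solution` with fields `flux`, `mu`, `sum_sq`, `status`.
#' @export
solve_fba_max_growth <- function(model, ec, tol = 1e-9) {
  sys <- fba_system(model, ec)
  probe <- function(mu_min) {
    if (!is.finite(mu_min))
      return(qp_point(sys, w = 1, d = rep(0, sys$n)))
    qp_point(sys, w = 1, d = rep(0, sys$n),
             A_extra = -sys$N[sys$i_bio, , drop = FALSE],
             b_extra = sys$v_p[sys$i_bio] - mu_min)
  }
  v0 <- probe(-Inf)
  if (is.null(v0)) {
    sol <- flux_solution(model, NULL, 0, "infeasible")
    sol$violation <- infeasibility_report(model, ec)
    return(sol)
  }
  lo <- v0[sys$i_bio]
  hi <- max(lo, 1e-3)
  while (!is.null(probe(hi)) && hi < 1e5) { lo <- hi; hi <- hi * 4 }
  if (hi >= 1e5) stop("unbounded growth rate; check model bounds")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is.null(probe(mid))) hi <- mid else lo <- mid
  }
  v <- probe(lo)
  flux_solution(model, v, 0, "optimal")
}

# short report of which fixed exchange values clash with the model
infeasibility_report <- function(model, ec) {
  fixed <- c(model$exchanges$lactate, model$exchanges$acetate,
             model$exchanges$pyruvate)
  vals <- c(-ec$v_lac_inflow, ec$v_act_flow, ec$v_pyr_flow)
  keep <- !is.na(vals)
  sprintf("fixed exchanges: %s",
          paste(fixed[keep], signif(vals[keep], 6), sep = "=",
                collapse = " "))
}

#' Dual-objective flux balance analysis
#'
#' Solves one pseudo-steady-state problem with the combined objective
#' maximize \eqn{\mu - w \sum v^2} (growth maximization traded against total
#' squared flux over all reactions, exchanges included) subject to
#' S v = 0, flux bounds, and the kinetically derived exchange equalities.
#' For `w > 0` this is a strictly concave quadratic program, so the local
#' optimum is global and unique; `w = 0` degenerates to the max-growth
#' linear program and is delegated to [solve_fba_max_growth()].
#'
#' @inheritParams solve_fba_max_growth
#' @param w weight of the flux-minimization objective (>= 0).
#' @return a `flux_solution`.
#' @export
#' @examples
#' toy <- build_toy_model()
#' ec <- exchange_constraints(10, 2, 1)
#' solve_dual_objective(toy, ec, w = 1e-4)
solve_dual_objective <- function(model, ec, w) {
  stopifnot(w >= 0)
  if (w == 0) return(solve_fba_max_growth(model, ec))
  sys <- fba_system(model, ec)
  d <- rep(0, sys$n); d[sys$i_bio] <- 1
  v <- qp_point(sys, w, d)
  if (is.null(v)) {
    sol <- flux_solution(model, NULL, w, "infeasible")
    sol$violation <- infeasibility_report(model, ec)
    return(sol)
  }
  flux_solution(model, v, w, "optimal")
}

#' Growth response along a weight grid
#'
#' Evaluates the dual-objective problem across a grid of weights, returning
#' one summary row per grid point. The growth rate is checked to be
#' non-increasing along increasing `w` (Pareto traversal); violations beyond
#' numerical tolerance raise a warning. Per-point solver failures are
#' recorded as `NA` rows with a warning rather than aborting the sweep.
#'
#' @inheritParams solve_fba_max_growth
#' @param w_grid non-negative weights (any order; sorted internally).
#' @return data frame with columns `w`, `mu`, `sum_sq`, `status`.
#' @export
growth_response_curve <- function(model, ec, w_grid) {
  stopifnot(length(w_grid) > 0, all(w_grid >= 0))
  w_grid <- sort(unique(w_grid))
  rows <- lapply(w_grid, function(w) {
    s <- solve_dual_objective(model, ec, w)
    data.frame(w = w, mu = s$mu, sum_sq = s$sum_sq, status = s$status)
  })
  out <- do.call(rbind, rows)
  if (all(out$status != "optimal"))
    warning("all grid points infeasible: ",
            infeasibility_report(model, ec))
  else if (any(out$status != "optimal"))
    warning(sum(out$status != "optimal"), " infeasible grid point(s)")
  mu_ok <- out$mu[out$status == "optimal"]
  if (length(mu_ok) > 1 &&
      any(diff(mu_ok) > 1e-6 * max(1, abs(mu_ok[1]))))
    warning("growth rate not non-increasing along the weight grid")
  out
}

#' Write a flux solution to TSV / JSON summary
#'
#' @param sol a `flux_solution`.
#' @param path output file (`.tsv` flux table).
#' @export
write_flux_tsv <- function(sol, path) {
  stopifnot(inherits(sol, "flux_solution"))
  df <- data.frame(reaction = names(sol$flux), flux = as.numeric(sol$flux))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_tsv
#' @export
flux_summary_json <- function(sol, path = NULL) {
  s <- list(status = sol$status, mu = sol$mu, sum_sq = sol$sum_sq, w = sol$w)
  if (is.null(path)) return(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
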