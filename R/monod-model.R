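#' Unit-step lag gate
#'
#' Dimensionless time-delay function describing the lag phase: 0 before the
#' lag time `t_L`, 1 from `t_L` onwards. It gates all four state derivatives
#' of the batch model, so trajectories are flat before growth starts.
#'
#' @param t time (h); vectorized.
#' @param t_L lag time (h).
#' @return 0/1 numeric vector.
#' @export
lag_gate <- function(t, t_L) as.numeric(t >= t_L)

#' Specific growth rates on each substrate
#'
#' Monod saturation kinetics per substrate:
#' \eqn{\mu_i = \mu_{max,i} C_i / (K_{s,i} + C_i)}.
#'
#' @param state named numeric with `X` (g DCW/L), `LACT`, `ACT`, `PYR` (mM).
#' @param p a [monod_params] vector.
#' @return named numeric `(mu_L, mu_A, mu_P)` in 1/h.
#' @export
specific_growth_rates <- function(state, p) {
  monod <- function(mu_max, C, Ks) {
    C <- max(C, 0)
    if (C == 0) return(0)
    mu_max * C / (Ks + C)
  }
  c(mu_L = monod(p[["mu_max_L"]], state[["LACT"]], p[["Ks_l"]]),
    mu_A = monod(p[["mu_max_A"]], state[["ACT"]], p[["Ks_a"]]),
    mu_P = monod(p[["mu_max_P"]], state[["PYR"]], p[["Ks_p"]]))
}

#' Overflow production rates
#'
#' Volumetric production rates of the overflow metabolites, first order in
#' both biomass and the source substrate (forced by the units of the rate
#' constants, L/(h g DCW)): acetate from lactate, pyruvate from lactate and
#' acetate from pyruvate.
#'
#' @inheritParams specific_growth_rates
#' @return named numeric `(r_AL, r_PL, r_AP)` in mmol/L/h.
#' @export
overflow_rates <- function(state, p) {
  X <- max(state[["X"]], 0)
  LACT <- max(state[["LACT"]], 0)
  PYR <- max(state[["PYR"]], 0)
  c(r_AL = p[["k_al"]] * X * LACT,
    r_PL = p[["k_pl"]] * X * LACT,
    r_AP = p[["k_ap"]] * X * PYR)
}

#' Time derivatives of the batch state
#'
#' Right-hand side of the four-ODE Monod batch model. Growth draws on all
#' three substrates with apparent yields; substrate consumption terms carry a
#' factor 1000 converting mol to mmol (yields are g DCW/mol, concentrations
#' mM). Lactate is additionally debited mole-per-mole for the overflow
#' production of pyruvate and acetate, and pyruvate for overflow acetate, so
#' overflow appearance is mass-balanced. The lag gate multiplies every
#' derivative.
#'
#' @param t time (h).
#' @inheritParams specific_growth_rates
#' @return named numeric derivative `(X, LACT, ACT, PYR)` per hour.
#' @export
monod_rhs <- function(t, state, p) {
  s <- lag_gate(t, p[["t_L"]])
  if (s == 0)
    return(c(X = 0, LACT = 0, ACT = 0, PYR = 0))
  X <- max(state[["X"]], 0)
  mu <- specific_growth_rates(state, p)
  r <- overflow_rates(state, p)
  dX <- (mu[["mu_L"]] + mu[["mu_A"]] + mu[["mu_P"]] - p[["k_e"]]) * X
  dLACT <- -(1000 * mu[["mu_L"]] / p[["Y_XL"]] * X + r[["r_PL"]] + r[["r_AL"]])
  dPYR <- r[["r_PL"]] - r[["r_AP"]] - 1000 * mu[["mu_P"]] / p[["Y_XP"]] * X
  dACT <- r[["r_AL"]] + r[["r_AP"]] - 1000 * mu[["mu_A"]] / p[["Y_XA"]] * X
  c(X = dX, LACT = dLACT, ACT = dACT, PYR = dPYR)
}

# positional fast path for the integrator: y = (X, LACT, ACT, PYR),
# q = c(mu_max_L, mu_max_A, mu_max_P, Y_XL, Y_XA, Y_XP, Ks_l, Ks_a, Ks_p,
#       k_al, k_pl, k_ap, k_e, t_L); gate handled by the caller (integration
# starts at t_L), so no branch here
monod_rhs_fast <- function(t, y, q) {
  X <- if (y[1] > 0) y[1] else 0
  L <- if (y[2] > 0) y[2] else 0
  A <- if (y[3] > 0) y[3] else 0
  P <- if (y[4] > 0) y[4] else 0
  muL <- q[1] * L / (q[7] + L)
  muA <- q[2] * A / (q[8] + A)
  muP <- q[3] * P / (q[9] + P)
  rAL <- q[10] * X * L
  rPL <- q[11] * X * L
  rAP <- q[12] * X * P
  list(c(
    (muL + muA + muP - q[13]) * X,
    -(1000 * muL / q[4] * X + rPL + rAL),
    rAL + rAP - 1000 * muA / q[6] * X,
    rPL - rAP - 1000 * muP / q[5] * X
  ))
}

#' Simulate a batch culture trajectory
#'
#' Integrates the Monod batch model on a dense time grid. States are held at
#' the initial condition until the lag time, then integrated with `lsoda`
#' (maximum step 0.05 h) with clipping of states at zero, which prevents
#' spurious negative concentrations near substrate exhaustion.
#'
#' @param p a [monod_params] vector.
#' @param init named numeric initial state `(X, LACT, ACT, PYR)`.
#' @param horizon simulation end time (h), used with `step` when `times` is
#'   not given.
#' @param step output grid spacing (h).
#' @param times optional explicit output time vector (overrides
#'   `horizon`/`step`); must be non-negative and strictly increasing.
#' @return A `batch_trajectory`: a data frame with columns
#'   `time_h, X, LACT, ACT, PYR` and attributes `params`, `init`, `solver`.
#' @export
#' @examples
#' tr <- simulate_batch(mr1_kinetics(), horizon = 34, step = 0.5)
#' head(tr)
simulate_batch <- function(p, init = c(X = 0.001, LACT = 30, ACT = 0, PYR = 0),
                           horizon = 34, step = 1 / 12, times = NULL) {
  p <- as_monod_params(p)
  init <- init[c("X", "LACT", "ACT", "PYR")]
  if (any(!is.finite(init)) || any(init < 0))
    stop("initial state must be finite and non-negative")
  if (is.null(times)) {
    if (horizon <= 0) stop("horizon must be positive")
    times <- seq(0, horizon, by = step)
    if (times[length(times)] < horizon) times <- c(times, horizon)
  }
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("times must be non-negative and strictly increasing")

  t_L <- p[["t_L"]]
  pre <- times[times < t_L]
  post <- times[times >= t_L]

  out <- NULL
  if (length(pre))
    out <- cbind(time = pre, matrix(init, nrow = length(pre), ncol = 4,
                                    byrow = TRUE,
                                    dimnames = list(NULL, names(init))))
  if (length(post)) {
    ode_times <- post
    # prepend the lag time as integration start unless the first output
    # point already sits on it (within solver resolution)
    lead <- post[1] > t_L + 1e-9
    if (lead) ode_times <- c(t_L, post)
    sol <- tryCatch(
      deSolve::ode(y = init, times = ode_times, func = monod_rhs_fast,
                   parms = as.numeric(p),
                   method = "lsoda", hmax = 0.05, rtol = 1e-8, atol = 1e-10),
      warning = function(w) stop("ODE solver failed: ", conditionMessage(w),
                                 call. = FALSE)
    )
    sol <- as.matrix(sol)
    if (nrow(sol) < length(ode_times))
      stop("ODE solver failed before reaching the horizon (t = ",
           signif(max(sol[, 1]), 4), " h)")
    if (lead) sol <- sol[-1, , drop = FALSE]
    colnames(sol)[1] <- "time"
    out <- rbind(out, sol)
  }
  traj <- data.frame(time_h = out[, "time"],
                     X = pmax(out[, "X"], 0), LACT = pmax(out[, "LACT"], 0),
                     ACT = pmax(out[, "ACT"], 0), PYR = pmax(out[, "PYR"], 0))
  structure(traj,
            params = p, init = init,
            solver = list(method = "lsoda", hmax = 0.05,
                          rtol = 1e-8, atol = 1e-10),
            class = c("batch_trajectory", "data.frame"))
}

#' Interpolate a batch trajectory and its derivatives
#'
#' Returns the state at arbitrary times by linear interpolation of the
#' simulated grid, or the exact analytic derivative of the model at those
#' times (evaluated from the right-hand side at the interpolated state).
#'
#' @param traj a `batch_trajectory`.
#' @param t times (h).
#' @param deriv if `TRUE`, return d(state)/dt instead of the state.
#' @return matrix with rows per time, columns `X, LACT, ACT, PYR`.
#' @export
trajectory_state <- function(traj, t, deriv = FALSE) {
  vars <- c("X", "LACT", "ACT", "PYR")
  st <- vapply(vars, function(v)
    stats::approx(traj$time_h, traj[[v]], xout = t, rule = 2)$y,
    numeric(length(t)))
  st <- matrix(st, ncol = 4, dimnames = list(NULL, vars))
  if (!deriv) return(st)
  p <- attr(traj, "params")
  t(vapply(seq_along(t), function(i) monod_rhs(t[i], st[i, ], p),
           numeric(4)))
}

#' Write a batch trajectory to TSV
#'
#' Tab-separated columns `time_h, biomass_gDCW_L, lactate_mM, acetate_mM,
#' pyruvate_mM` preceded by `#`-prefixed provenance header lines recording
#' the kinetic parameters, initial state and solver settings.
#'
#' @param traj a `batch_trajectory`.
#' @param path output file.
#' @export
write_trajectory_tsv <- function(traj, path) {
  p <- attr(traj, "params")
  init <- attr(traj, "init")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# dynafba batch trajectory"),
    paste0("# params: ", paste(names(unclass(p)), signif(as.numeric(p), 8),
                               sep = "=", collapse = " ")),
    paste0("# init: ", paste(names(init), signif(init, 8),
                             sep = "=", collapse = " ")),
    paste0("# solver: lsoda hmax=0.05")), con)
  df <- data.frame(time_h = traj$time_h, biomass_gDCW_L = traj$X,
                   lactate_mM = traj$LACT, acetate_mM = traj$ACT,
                   pyruvate_mM = traj$PYR)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read batch measurements from delimited text
#'
#' Expects header columns `time_h, biomass_gDCW_L, lactate_mM, acetate_mM,
#' pyruvate_mM` (comma- or tab-separated; missing cells allowed). Returns a
#' `batch_measurements` object: per-variable sample times and values plus the
#' per-variable normalization constant (the maximum measured value), as used
#' by the normalized least-squares objective.
#'
#' @param path CSV/TSV file.
#' @return a `batch_measurements` list.
#' @export
read_measurements <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = TRUE)
  as_batch_measurements(df)
}

#' @rdname read_measurements
#' @param df a data frame with the columns above (or already named
#'   `time_h, X, LACT, ACT, PYR`).
#' @export
as_batch_measurements <- function(df) {
  ren <- c(biomass_gDCW_L = "X", lactate_mM = "LACT",
           acetate_mM = "ACT", pyruvate_mM = "PYR")
  for (nm in names(ren))
    if (nm %in% names(df)) names(df)[names(df) == nm] <- ren[[nm]]
  if (!"time_h" %in% names(df)) stop("measurements need a time_h column")
  vars <- intersect(c("X", "LACT", "ACT", "PYR"), names(df))
  if (!length(vars)) stop("no measured variable columns found")
  m <- lapply(vars, function(v) {
    keep <- is.finite(df[[v]])
    list(time = df$time_h[keep], value = df[[v]][keep])
  })
  names(m) <- vars
  for (v in vars) {
    tt <- m[[v]]$time
    if (length(tt) && is.unsorted(tt, strictly = TRUE))
      stop("sample times for ", v, " must be strictly increasing")
  }
  norm <- vapply(m, function(x) max(x$value), numeric(1))
  if (any(norm <= 0))
    stop("normalization constants must be positive (all-zero variable?)")
  structure(list(series = m, norm = norm),
            class = "batch_measurements")
}

#' @export
print.batch_measurements <- function(x, ...) {
  cat("Batch measurements:",
      paste(sprintf("%s (n=%d, max=%.4g)", names(x$series),
                    vapply(x$series, function(s) length(s$time), 1L),
                    x$norm), collapse = ", "), "\n")
  invisible(x)
}

#' Write batch measurements to CSV
#'
#' Inverse of [read_measurements()]; variables sampled at different times are
#' merged on the union grid with empty cells for missing samples.
#'
#' @param m a `batch_measurements` object.
#' @param path output file.
#' @export
write_measurements_csv <- function(m, path) {
  tt <- sort(unique(unlist(lapply(m$series, `[[`, "time"))))
  cols <- c(X = "biomass_gDCW_L", LACT = "lactate_mM",
            ACT = "acetate_mM", PYR = "pyruvate_mM")
  df <- data.frame(time_h = tt)
  for (v in names(m$series)) {
    s <- m$series[[v]]
    df[[cols[[v]]]] <- s$value[match(tt, s$time)]
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
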