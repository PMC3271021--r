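#' Tracer and labeling-experiment specification
#'
#' @param substrate fed metabolite id (default `"lac"`).
#' @param positions labeled carbon position(s) of the tracer (e.g. `3` for
#'   \[3-13C\] lactate).
#' @param purity isotopic purity of the labeled position(s), in (0, 1].
#' @param natural_abundance if `TRUE`, unlabeled carbon positions carry the
#'   natural 1.07% 13C abundance (off by default).
#' @param harvest_times biomass harvest times (h) at which protein-bound
#'   amino-acid labeling is reported.
#' @return a `labeling_experiment` object.
#' @export
labeling_experiment <- function(substrate = "lac", positions = 3,
                                purity = 0.98, natural_abundance = FALSE,
                                harvest_times = c(24, 30)) {
  stopifnot(purity > 0, purity <= 1)
  structure(list(substrate = substrate, positions = positions,
                 purity = purity, natural_abundance = natural_abundance,
                 harvest_times = harvest_times),
            class = "labeling_experiment")
}

#' Positional-label isotopomer distribution of a tracer
#'
#' @param n_carbon carbon count of the substrate.
#' @param positions labeled positions.
#' @param purity labeling probability at those positions.
#' @param na_p 13C probability at the remaining positions (0, or natural
#'   abundance).
#' @return an IDV of length `2^n_carbon` (unlabeled state first).
#' @export
tracer_idv <- function(n_carbon, positions, purity, na_p = 0) {
  p <- rep(na_p, n_carbon)
  p[positions] <- purity
  idv <- 1 # carbon 1 is the fastest-varying bit of the state index
  for (k in seq_len(n_carbon))
    idv <- c(idv * (1 - p[k]), idv * p[k])
  idv
}

#' Collapse an isotopomer distribution to a mass distribution
#'
#' `M+k` is the summed fraction of isotopomers with `k` labeled carbons.
#' Optionally convolves the result with the binomial natural-abundance
#' distribution of 13C over the fragment's carbon skeleton (carbon only;
#' the \[M-57\]+ fragment convention carries all amino-acid carbons).
#'
#' @param idv an IDV (length a power of 2).
#' @param natural_abundance apply the carbon natural-abundance convolution.
#' @return an MDV of length `n + 1`.
#' @export
#' @examples
#' idv_to_mdv(c(0, 0.5, 0.5, 0))  # two singly labeled isotopomers
idv_to_mdv <- function(idv, natural_abundance = FALSE) {
  n <- round(log2(length(idv)))
  stopifnot(2^n == length(idv))
  bits <- vapply(seq_along(idv) - 1L, function(s)
    sum(as.integer(intToBits(s))[seq_len(max(n, 1))]), 1L)
  mdv <- vapply(0:n, function(k) sum(idv[bits == k]), 1)
  if (natural_abundance && n > 0) {
    na <- stats::dbinom(0:n, n, 0.0107)
    conv <- numeric(n + 1)
    for (k in 0:n) for (j in 0:(n - k))
      conv[k + j + 1] <- conv[k + j + 1] + mdv[k + 1] * na[j + 1]
    mdv <- conv / sum(conv)
  }
  mdv
}

# Contribution plan for one interval: flux-weighted production terms per
# metabolite. Designated reversible pathways are augmented by a
# bidirectional exchange flux v_exch = (exch/(1-exch)) * exch_ref added to
# both directions on top of the net flux; the fixed unit reference scale
# (13CFLUX "xch01" convention) keeps the exchange effective even where the
# flux solution keeps the net flux minimal, which is precisely the regime
# the coefficients describe. Fitted coefficients are convention-dependent.
build_contributions <- function(cmaps, v, exch, inputs, ex_feed,
                                flux_tol = 1e-9, exch_ref = 1) {
  contribs <- list()
  add <- function(met, weight, sub_mets, M) {
    if (weight <= flux_tol) return()
    contribs[[met]] <<- c(contribs[[met]],
                          list(list(w = weight, subs = sub_mets, M = M)))
  }
  n_tr <- length(cmaps$fwd)
  for (i in seq_len(n_tr)) {
    tr <- cmaps$fwd[[i]]
    f <- if (tr$rxn %in% names(v)) v[[tr$rxn]] else 0
    e <- if (tr$rxn %in% names(exch)) exch[[tr$rxn]] else 0
    vx <- if (e > 0) e / (1 - e) * exch_ref else 0
    f_fwd <- max(f, 0) + vx
    f_rev <- max(-f, 0) + vx
    if (f_fwd > flux_tol)
      for (op in tr$ops) add(op$met, f_fwd * tr$weight, tr$sub_mets, op$M)
    if (f_rev > flux_tol) {
      rv <- cmaps$rev[[i]]
      for (op in rv$ops) add(op$met, f_rev * rv$weight, rv$sub_mets, op$M)
    }
  }
  # external feeds through exchange uptake (negative exchange flux)
  for (m in names(ex_feed)) {
    f <- ex_feed[[m]]
    if (f > flux_tol)
      add(m, f, character(0), inputs[[m]])
  }
  contribs
}

#' Solve the pseudo-steady-state isotopomer balance of one interval
#'
#' Finds the fixed point of the flux-weighted isotopomer balance: for every
#' produced metabolite, its IDV equals the production-flux-weighted mean of
#' the mapped precursor distributions (joint distributions for
#' multi-substrate reactions). Each designated reversible pathway is
#' augmented with a bidirectional flux `v_exch = exch/(1-exch) * exch_ref`
#' added to both directions, mixing product and substrate labeling while
#' leaving the net flux unchanged; the fixed unit reference scale
#' (`exch_ref`, mmol/g DCW/h) follows the normalized-exchange convention
#' of 13C flux analysis, so a pathway can exchange label even where the
#' flux solution keeps its net flux minimal. Iteration stops when the
#' largest IDV change falls below `tol`.
#'
#' @param model a `stoich_model` (supplies the exchange-reaction roles).
#' @param v named flux vector (one dFBA interval).
#' @param am an `atom_map` (or precompiled maps from an earlier call).
#' @param inputs named list of feed IDVs for exchange-borne metabolites
#'   (e.g. `lac` = tracer, `ace`/`pyr` = medium pools, `co2` unlabeled).
#' @param exch named exchange coefficients in \[0, 1), e.g. `c(ME2 = 0.862)`.
#' @param init optional warm-start IDVs.
#' @param exch_ref reference scale of the exchange-flux convention
#'   (mmol/g DCW/h).
#' @param tol convergence tolerance on IDV entries.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return list with `idvs` (named list of IDVs), `iterations`,
#'   `unproduced` (consumed-but-unproduced metabolites, flagged).
#' @export
solve_interval_idvs <- function(model, v, am, inputs = list(),
                                exch = numeric(), init = NULL,
                                exch_ref = 1, tol = 1e-10, max_iter = 5000) {
  cmaps <- if (inherits(am, "atom_map")) compile_atom_maps(am) else am
  ex_feed <- exchange_feeds(model, v)
  ex_feed <- ex_feed[names(ex_feed) %in% names(cmaps$n_carbon)]
  for (m in names(ex_feed))
    if (is.null(inputs[[m]]))
      inputs[[m]] <- unlabeled_idv(cmaps$n_carbon[[m]])
  contribs <- build_contributions(cmaps, v, exch, inputs, ex_feed,
                                  exch_ref = exch_ref)
  mets <- names(contribs)
  idvs <- lapply(mets, function(m) {
    if (!is.null(init[[m]])) init[[m]] else unlabeled_idv(cmaps$n_carbon[[m]])
  })
  names(idvs) <- mets
  wsum <- lapply(contribs, function(cc) sum(vapply(cc, `[[`, 0, "w")))
  get_idv <- function(m) {
    if (!is.null(idvs[[m]])) return(idvs[[m]])
    if (!is.null(inputs[[m]])) return(inputs[[m]])
    unlabeled_idv(cmaps$n_carbon[[m]])
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    for (m in mets) {
      acc <- 0
      for (cc in contribs[[m]]) {
        if (!length(cc$subs)) { acc <- acc + cc$w * cc$M; next }
        joint <- get_idv(cc$subs[1])
        if (length(cc$subs) > 1)
          for (s in cc$subs[-1])
            joint <- as.vector(outer(joint, get_idv(s)))
        acc <- acc + cc$w * drop(cc$M %*% joint)
      }
      new <- acc / wsum[[m]]
      # renormalize: bimolecular terms multiply tiny floating-point drift
      # in the IDV sums, which would otherwise compound through cycles
      new <- new / sum(new)
      delta <- max(delta, max(abs(new - idvs[[m]])))
      idvs[[m]] <- new
    }
    if (delta < tol) break
    if (iter >= max_iter)
      stop(sprintf("isotopomer balance did not converge (residual %.3g)",
                   delta))
  }
  # consumed-but-unproduced metabolites, flagged (left unlabeled)
  consumed <- unique(unlist(lapply(cmaps$fwd, function(tr)
    if ((if (tr$rxn %in% names(v)) v[[tr$rxn]] else 0) > 1e-9)
      tr$sub_mets)))
  unproduced <- setdiff(intersect(consumed, names(cmaps$n_carbon)),
                        c(mets, names(inputs)))
  list(idvs = idvs, iterations = iter, unproduced = unproduced)
}

unlabeled_idv <- function(n) c(1, numeric(2^n - 1))

# net feed flux (uptake magnitude) per internal metabolite behind each
# model exchange reaction
exchange_feeds <- function(model, v) {
  feeds <- list()
  for (ex in unlist(model$exchanges)) {
    if (!ex %in% names(v)) next
    met <- model$mets[model$S[, ex] != 0]
    if (length(met) != 1) next
    if (v[[ex]] < 0) feeds[[met]] <- -v[[ex]]
  }
  feeds
}

#' Simulate dynamic 13C labeling of proteinogenic amino acids
#'
#' Propagates tracer labeling through the dynamic flux series of a
#' [run_dfba()] result: each pseudo-steady-state interval is solved for its
#' transient intracellular isotopomer distributions (warm-started from the
#' previous interval), extracellular acetate and pyruvate pools accumulate
#' secreted label and feed it back during the reuse phase, and
#' protein-bound amino-acid labeling integrates the precursor
#' distributions weighted by biomass production:
#' `IDV_int(t') = sum(dX(t) p(t) IDV(t)) / sum(dX(t) p(t))` over `t <= t'`.
#'
#' @param run a `dfba_run`.
#' @param am an `atom_map`, e.g. [toy_atom_maps()].
#' @param experiment a [labeling_experiment].
#' @param exch named exchange coefficients (pathway reversibility), e.g.
#'   `c(ME2 = 0.862)`.
#' @param aa_map amino-acid precursor table, see [toy_amino_acid_map()].
#' @param exch_ref reference scale of the exchange-flux convention
#'   (mmol/g DCW/h).
#' @param store_series keep the per-interval cumulative IDVs.
#' @return a `labeling_sim` object with `idv_int` (final cumulative IDV per
#'   amino acid), `snapshots` (cumulative IDVs at each harvest time),
#'   `mdv` (per harvest time, fragment x mass-shift table), `pools`
#'   (final extracellular pool IDVs) and optionally `series`.
#' @export
simulate_labeling <- function(run, am, experiment = labeling_experiment(),
                              exch = numeric(),
                              aa_map = toy_amino_acid_map(),
                              exch_ref = 1, store_series = FALSE) {
  stopifnot(inherits(run, "dfba_run"))
  cmaps <- compile_atom_maps(am)
  model <- run$model
  iv <- run$intervals
  dt <- run$cfg$dt
  na_p <- if (experiment$natural_abundance) 0.0107 else 0
  tracer <- tracer_idv(cmaps$n_carbon[[experiment$substrate]],
                       experiment$positions, experiment$purity, na_p)

  # extracellular pools follow the kinetic trajectory concentrations
  bounds <- c(iv$t_mid - dt / 2, iv$t_mid[nrow(iv)] + dt / 2)
  conc <- trajectory_state(run$trajectory, bounds)
  X_mid <- trajectory_state(run$trajectory, iv$t_mid)[, "X"]
  pools <- list(
    ace = list(conc_col = "ACT", idv = unlabeled_idv(cmaps$n_carbon[["ace"]])),
    pyr = list(conc_col = "PYR", idv = unlabeled_idv(cmaps$n_carbon[["pyr"]])))
  pool_ex <- c(ace = model$exchanges$acetate, pyr = model$exchanges$pyruvate)

  num <- den <- stats::setNames(vector("list", nrow(aa_map)), aa_map$aa)
  for (a in aa_map$aa) den[[a]] <- 0
  snapshots <- list()
  series <- if (store_series) vector("list", nrow(iv)) else NULL
  interval_idvs <- if (store_series) vector("list", nrow(iv)) else NULL
  idvs_prev <- NULL
  harvest_left <- sort(experiment$harvest_times)

  for (i in seq_len(nrow(iv))) {
    t_end <- iv$t_mid[i] + dt / 2
    v <- run$fluxes[i, ]
    active <- iv$status[i] == "optimal" && max(abs(v), na.rm = TRUE) > 1e-9
    if (active) {
      inputs <- list(lac = tracer, ace = pools$ace$idv, pyr = pools$pyr$idv,
                     co2 = unlabeled_idv(1))
      sol <- solve_interval_idvs(model, v, cmaps, inputs = inputs,
                                 exch = exch, init = idvs_prev,
                                 exch_ref = exch_ref)
      idvs_prev <- sol$idvs
      # protein accumulation, weighted by dX(t) * p(t)
      v_bio <- v[[model$biomass]]
      if (v_bio > 0 && iv$dX[i] > 0) {
        for (j in seq_len(nrow(aa_map))) {
          a <- aa_map$aa[j]; prec <- aa_map$precursor[j]
          idv_p <- sol$idvs[[prec]]
          if (is.null(idv_p))
            idv_p <- unlabeled_idv(cmaps$n_carbon[[prec]])
          w <- iv$dX[i] * aa_map$coeff[j] * v_bio
          num[[a]] <- if (is.null(num[[a]])) w * idv_p else
            num[[a]] + w * idv_p
          den[[a]] <- den[[a]] + w
        }
      }
      # pool mixing: secretion adds internal label; uptake leaves IDV as is
      for (pn in names(pools)) {
        vex <- v[[pool_ex[[pn]]]]
        if (vex > 1e-12) {
          add <- vex * X_mid[i] * dt
          c0 <- conc[i, pools[[pn]]$conc_col]
          idv_int <- idvs_prev[[pn]]
          if (!is.null(idv_int)) {
            mix <- c0 * pools[[pn]]$idv + add * idv_int
            pools[[pn]]$idv <- mix / sum(mix)
          }
        }
      }
    }
    if (store_series) {
      series[[i]] <- lapply(stats::setNames(aa_map$aa, aa_map$aa),
                            function(a)
                              if (den[[a]] > 0) num[[a]] / den[[a]] else NULL)
      interval_idvs[[i]] <- if (active) idvs_prev else list()
    }
    while (length(harvest_left) && t_end >= harvest_left[1] - 1e-9) {
      snapshots[[format(harvest_left[1])]] <-
        lapply(stats::setNames(aa_map$aa, aa_map$aa), function(a)
          if (den[[a]] > 0) num[[a]] / den[[a]] else NULL)
      harvest_left <- harvest_left[-1]
    }
  }
  idv_int <- lapply(stats::setNames(aa_map$aa, aa_map$aa), function(a)
    if (den[[a]] > 0) num[[a]] / den[[a]] else NULL)
  mdv <- lapply(snapshots, function(sn)
    lapply(Filter(Negate(is.null), sn), idv_to_mdv,
           natural_abundance = FALSE))
  structure(list(idv_int = idv_int, snapshots = snapshots, mdv = mdv,
                 pools = lapply(pools, `[[`, "idv"), series = series,
                 interval_idvs = interval_idvs,
                 experiment = experiment, exch = exch),
            class = "labeling_sim")
}

#' @export
print.labeling_sim <- function(x, ...) {
  cat("Dynamic labeling simulation;",
      length(x$mdv), "harvest snapshot(s)\n")
  for (tn in names(x$mdv)) {
    cat(" t =", tn, "h: M+1 fractions ",
        paste(names(x$mdv[[tn]]),
              vapply(x$mdv[[tn]], function(m) sprintf("%.3f", m[2]), ""),
              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Time-integrated amino-acid labeling from an IDV series
#'
#' Explicit re-summation form of the protein-labeling integral: given
#' per-interval precursor IDVs and the interval table of a dFBA run,
#' returns `sum(dX p IDV) / sum(dX p)` per amino acid. Used as the
#' cross-check for the accumulation performed inside
#' [simulate_labeling()].
#'
#' @param idv_series list (per interval) of named lists of precursor IDVs.
#' @param fts interval table with columns `dX` and the biomass flux column
#'   `v_bio`, aligned with `idv_series`.
#' @param aa_map amino-acid precursor table.
#' @return named list of integrated IDVs.
#' @export
accumulate_protein_labeling <- function(idv_series, fts,
                                        aa_map = toy_amino_acid_map()) {
  stopifnot(length(idv_series) == nrow(fts))
  out <- list()
  for (j in seq_len(nrow(aa_map))) {
    a <- aa_map$aa[j]; prec <- aa_map$precursor[j]
    num <- 0; den <- 0
    for (i in seq_along(idv_series)) {
      idv <- idv_series[[i]][[prec]]
      if (is.null(idv)) next
      w <- fts$dX[i] * aa_map$coeff[j] * fts$v_bio[i]
      if (!is.finite(w) || w <= 0) next
      num <- num + w * idv; den <- den + w
    }
    if (den == 0) stop("zero cumulative biomass for ", a)
    out[[a]] <- num / den
  }
  out
}

#' Sigma-weighted fit score between simulated and measured MDVs
#'
#' `sum over fragments and mass shifts of ((sim - exp)/sigma)^2`, with a
#' constant GC-MS measurement error `sigma` (default 0.02).
#'
#' @param sim,exp named lists of MDVs with matching fragment sets.
#' @param sigma measurement standard deviation.
#' @return the weighted residual sum of squares.
#' @export
score_fit <- function(sim, exp, sigma = 0.02) {
  if (!setequal(names(sim), names(exp)))
    stop("mismatched fragment lists: ",
         paste(symdiff_chr(names(sim), names(exp)), collapse = ", "))
  total <- 0
  for (f in names(sim)) {
    if (length(sim[[f]]) != length(exp[[f]]))
      stop("mass-shift length mismatch for fragment ", f)
    total <- total + sum(((sim[[f]] - exp[[f]]) / sigma)^2)
  }
  total
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' Write / read MDV tables as TSV
#'
#' Columns `fragment, M0, M1, ...` (ragged tails left empty for fragments
#' with fewer carbons).
#'
#' @param mdvs named list of MDVs.
#' @param path file path.
#' @export
write_mdv_tsv <- function(mdvs, path) {
  nmax <- max(vapply(mdvs, length, 1L))
  rows <- lapply(names(mdvs), function(f) {
    v <- c(mdvs[[f]], rep(NA, nmax - length(mdvs[[f]])))
    data.frame(fragment = f, t(v))
  })
  df <- do.call(rbind, rows)
  names(df) <- c("fragment", paste0("M", seq_len(nmax) - 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_mdv_tsv
#' @export
read_mdv_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    v <- suppressWarnings(as.numeric(df[i, -1]))
    v[!is.na(v)]
  })
  stats::setNames(out, df$fragment)
}
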