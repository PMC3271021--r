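#' Molecule-level Monte Carlo label propagation
#'
#' Stochastic cross-check for the deterministic isotopomer balance: every
#' produced metabolite is represented by a pool of individual molecules
#' with explicit positional labeling states. Each sweep resamples every
#' pool — a molecule picks its producing pathway with probability
#' proportional to the production flux, draws one random molecule from
#' each substrate pool (or from the feed distribution) and inherits its
#' carbons through the atom transitions. After the sweeps the pool
#' fractions estimate the stationary isotopomer distributions
#' independently of the fixed-point iteration.
#'
#' The estimator runs `n_chains` independent replicate chains (the total
#' molecule count `n_mol` is split across them) and reports the pooled
#' mean with the empirical standard error across chains. Within one chain
#' molecules share ancestry, so a naive binomial standard error would
#' understate the sampling error severalfold; the between-chain spread
#' captures the full variance.
#'
#' @inheritParams solve_interval_idvs
#' @param n_mol total molecules per metabolite across all chains (>= 1e5
#'   recommended for comparisons).
#' @param sweeps resampling sweeps per chain, including burn-in; slow
#'   mixing only arises with near-unity exchange coefficients, for which
#'   the default is ample at desk scale.
#' @param avg_last chain estimates average the pool fractions over this
#'   many final sweeps (the earlier sweeps are burn-in), which suppresses
#'   the pool-level sampling fluctuation of a single snapshot.
#' @param n_chains independent replicate chains.
#' @param seed RNG seed.
#' @return list with `idvs` (pooled empirical IDVs), `se` (per-entry
#'   empirical standard errors of the pooled mean), `enrichment`
#'   (per-metabolite mean labeled-carbon count, with `enrichment_se`),
#'   `n_mol`, `n_chains`.
#' @export
mc_label_propagation <- function(model, v, am, inputs = list(),
                                 exch = numeric(), exch_ref = 1,
                                 n_mol = 1e5, sweeps = 200, avg_last = 100,
                                 n_chains = 8, seed = 1) {
  cmaps <- if (inherits(am, "atom_map")) compile_atom_maps(am) else am
  ex_feed <- exchange_feeds(model, v)
  ex_feed <- ex_feed[names(ex_feed) %in% names(cmaps$n_carbon)]
  for (m in names(ex_feed))
    if (is.null(inputs[[m]]))
      inputs[[m]] <- unlabeled_idv(cmaps$n_carbon[[m]])
  contribs <- build_contributions(cmaps, v, exch, inputs, ex_feed,
                                  exch_ref = exch_ref)
  mets <- names(contribs)
  # per-contribution product lookup table: joint substrate state -> product
  luts <- lapply(contribs, function(cc) lapply(cc, function(c1) {
    if (!length(c1$subs)) return(NULL)
    apply(c1$M, 2, which.max)
  }))
  dims <- lapply(contribs, function(cc) lapply(cc, function(c1)
    if (length(c1$subs)) 2^cmaps$n_carbon[c1$subs] else NULL))
  wts <- lapply(contribs, function(cc) vapply(cc, `[[`, 0, "w"))

  n_per_chain <- ceiling(n_mol / n_chains)
  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    nm <- n_per_chain
    draw_input <- function(idv, k)
      sample.int(length(idv), k, replace = TRUE, prob = idv)
    pools <- stats::setNames(lapply(mets, function(m) rep(1L, nm)), mets)
    counts <- stats::setNames(lapply(mets, function(m)
      numeric(2^cmaps$n_carbon[[m]])), mets)
    n_avg <- 0L
    for (sw in seq_len(sweeps)) {
      new_pools <- pools
      for (m in mets) {
        cc <- contribs[[m]]
        n_per <- stats::rmultinom(1, nm, wts[[m]])[, 1]
        out <- integer(0)
        for (ci in seq_along(cc)) {
          k <- n_per[ci]
          if (k == 0) next
          c1 <- cc[[ci]]
          if (!length(c1$subs)) { # feed: M holds the input IDV
            out <- c(out, draw_input(c1$M, k))
            next
          }
          joint <- integer(k); mult <- 1L
          for (si in seq_along(c1$subs)) {
            s <- c1$subs[si]
            pool_s <- pools[[s]]
            st <- if (!is.null(pool_s))
              pool_s[sample.int(length(pool_s), k, replace = TRUE)]
            else draw_input(inputs[[s]], k)
            joint <- joint + (st - 1L) * mult
            mult <- mult * dims[[m]][[ci]][si]
          }
          out <- c(out, luts[[m]][[ci]][joint + 1L])
        }
        new_pools[[m]] <- out
      }
      pools <- new_pools
      if (sw > sweeps - avg_last) {
        n_avg <- n_avg + 1L
        for (m in mets)
          counts[[m]] <- counts[[m]] +
            tabulate(pools[[m]], nbins = 2^cmaps$n_carbon[[m]])
      }
    }
    lapply(counts, function(ct) ct / (n_avg * nm))
  }
  chains <- lapply(seq_len(n_chains), function(ch)
    stats::setNames(run_chain(seed + 1000L * ch), mets))
  idvs <- lapply(mets, function(m)
    Reduce(`+`, lapply(chains, `[[`, m)) / n_chains)
  se <- lapply(mets, function(m) {
    mat <- do.call(rbind, lapply(chains, `[[`, m))
    apply(mat, 2, stats::sd) / sqrt(n_chains)
  })
  names(idvs) <- names(se) <- mets
  # per-metabolite mean labeled-carbon count: one scalar statistic per
  # metabolite, for calibrated oracle comparisons
  nbits <- function(len) vapply(seq_len(len) - 1L, function(s)
    sum(as.integer(intToBits(s))), 1L)
  enr <- vapply(mets, function(m) {
    b <- nbits(length(idvs[[m]]))
    sum(idvs[[m]] * b)
  }, 1)
  enr_se <- vapply(mets, function(m) {
    b <- nbits(length(idvs[[m]]))
    per_chain <- vapply(chains, function(ch) sum(ch[[m]] * b), 1)
    stats::sd(per_chain) / sqrt(n_chains)
  }, 1)
  list(idvs = idvs, se = se, enrichment = enr, enrichment_se = enr_se,
       n_mol = n_per_chain * n_chains, n_chains = n_chains)
}
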