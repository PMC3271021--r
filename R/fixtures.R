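#' Default batch experiment conditions
#'
#' Study conditions for the aerobic *S. oneidensis* MR-1 batch reference
#' case: the published kinetic parameter set, an initial state of 30 mM
#' lactate with a small inoculum (0.1% transfer, taken as 0.001 g DCW/L),
#' no initial overflow products, hourly sampling over a 34-h horizon and a
#' 2% relative measurement noise level (the GC-MS/enzyme-assay scale error).
#'
#' @return list with `params` ([monod_params]), `init` (named state),
#'   `noise` (relative level, fraction of each variable's maximum),
#'   `schedule` (sampling times, h), `horizon` (h).
#' @export
#' @examples
#' ex <- default_experiment()
#' ex$params["mu_max_L"]
default_experiment <- function() {
  list(params = mr1_kinetics(),
       init = c(X = 0.001, LACT = 30, ACT = 0, PYR = 0),
       noise = 0.02,
       schedule = seq(0, 34, by = 1),
       horizon = 34)
}

#' Generate synthetic noisy batch measurements
#'
#' Simulates the Monod batch model and samples it on a schedule, adding
#' independent Gaussian noise with standard deviation `noise` times the
#' variable's maximum simulated value (i.e. noise on the normalized scale
#' used in fitting), truncated at zero to preserve non-negativity. With 2%
#' noise the truncation bias is immaterial. Deterministic for a fixed seed.
#'
#' @param p a [monod_params] vector.
#' @param init initial state.
#' @param schedule sampling times (h).
#' @param noise relative noise level (0 = noise-free).
#' @param seed RNG seed.
#' @return a `batch_measurements` object (see [read_measurements()]).
#' @export
generate_noisy_batch <- function(p, init = c(X = 0.001, LACT = 30,
                                             ACT = 0, PYR = 0),
                                 schedule = seq(0, 34, by = 1),
                                 noise = 0.02, seed = 1) {
  stopifnot(noise >= 0)
  schedule <- sort(unique(schedule))
  traj <- simulate_batch(p, init = init,
                         times = if (schedule[1] > 0) c(0, schedule)
                                 else schedule)
  set.seed(seed)
  df <- data.frame(time_h = schedule)
  for (v in c("X", "LACT", "ACT", "PYR")) {
    y <- stats::approx(traj$time_h, traj[[v]], xout = schedule)$y
    if (noise > 0)
      y <- pmax(y + stats::rnorm(length(y), 0, noise * max(y)), 0)
    df[[v]] <- y
  }
  as_batch_measurements(df)
}
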