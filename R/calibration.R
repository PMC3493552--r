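#' @name calibration
#' @title Calibrating the ACE model against assemblage-level variation
#'
#' @description
#' Archaeological assemblages are summarised by the coefficient of
#' variation (CV) of an artifact dimension pooled over many lineages and
#' time depths — e.g. a CV of 0.30 for handaxe length and 0.23 for breadth
#' in a large Acheulean database.  The calibration functions connect the
#' experimentally measured copying-error sd to such summaries through
#' simulation: how many generations does the model need to reach a target
#' pooled CV, and conversely what copying-error sd would be needed to
#' produce the target CV over a given time depth.  Both work on the median
#' pooled CV over a set of seeded replicate ensembles (default 25 replicates
#' of 100 chains starting at size 1), which removes single-run seed noise
#' while keeping the scale of the underlying simulation.
NULL

# Seeds for replicate ensembles, derived from one base seed and kept well
# inside 32-bit integer range.
replicate_seeds <- function(seed, replicates) {
  (as.integer(seed) %% 1000000L) * 1000L + seq_len(replicates)
}

# Median (across replicate ensembles) pooled CV at every horizon 1..max_T.
# Returns a matrix: rows = horizon, cols = replicate.
replicate_cv_trajectories <- function(sigma, max_T, n_chains, replicates,
                                      seed, x0 = 1) {
  vapply(replicate_seeds(seed, replicates), function(s) {
    ens <- simulate_ensemble(x0, sigma, n_chains, max_T, s)
    pooled_cv_trajectory(ens)
  }, numeric(max_T))
}

#' Generations needed for the pooled CV to reach a target
#'
#' Finds the smallest horizon `T <= max_T` at which the median pooled CV —
#' over `replicates` independently seeded ensembles of `n_chains` chains
#' starting at `x0` — reaches `cv_target`.  The CV pools all values from
#' generations 1..T of all chains (see [pooled_cv()]).  Because the pooled
#' CV at every horizon up to `max_T` is obtained from a single simulation
#' pass per replicate, the search simply scans all horizons.
#'
#' @param sigma Copying-error sd, strictly positive (with `sigma = 0` the
#'   CV stays 0 and the target is reported as not reached).
#' @param cv_target Target pooled CV, positive.
#' @param n_chains Chains per replicate ensemble (default 100).
#' @param replicates Number of seeded replicate ensembles (default 25).
#' @param seed Base seed; replicate seeds are derived from it.
#' @param max_T Largest horizon scanned (default 1000).
#' @param x0 Starting size (default 1).
#' @return An `ace_calibration` object.  `solved_value` is the generation
#'   count, or `NA` with `reached = FALSE` if the target is not reached by
#'   `max_T`; `cv_at_solution` is the median pooled CV there, and
#'   `cv_spread` the range of replicate CVs at the solution.
#' @examples
#' generations_to_cv(0.0343, 0.30, replicates = 5, seed = 1, max_T = 300)
#' @export
generations_to_cv <- function(sigma, cv_target, n_chains = 100,
                              replicates = 25, seed = 1, max_T = 1000,
                              x0 = 1) {
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(cv_target, "cv_target", lower = 0, strict = TRUE)
  check_scalar(max_T, "max_T", lower = 1, integer = TRUE)
  if (sigma == 0) {
    return(new_calibration(solved_value = NA_real_, reached = FALSE,
                           target_cv = cv_target, fixed_parameter =
                             c(sigma = sigma), n_chains = n_chains,
                           replicates = replicates, seed = seed,
                           cv_at_solution = 0, cv_spread = c(0, 0),
                           solved_for = "generations"))
  }
  trajs <- replicate_cv_trajectories(sigma, max_T, n_chains, replicates,
                                     seed, x0)
  med <- apply(trajs, 1L, stats::median)
  hit <- which(med >= cv_target)
  if (length(hit) == 0) {
    return(new_calibration(solved_value = NA_real_, reached = FALSE,
                           target_cv = cv_target,
                           fixed_parameter = c(sigma = sigma),
                           n_chains = n_chains, replicates = replicates,
                           seed = seed, cv_at_solution = med[max_T],
                           cv_spread = range(trajs[max_T, ]),
                           solved_for = "generations"))
  }
  T_star <- hit[1]
  new_calibration(solved_value = T_star, reached = TRUE,
                  target_cv = cv_target, fixed_parameter = c(sigma = sigma),
                  n_chains = n_chains, replicates = replicates, seed = seed,
                  cv_at_solution = med[T_star],
                  cv_spread = range(trajs[T_star, ]),
                  solved_for = "generations")
}

# Median pooled CV at a single horizon T (over replicate ensembles).
median_pooled_cv <- function(sigma, T, n_chains, replicates, seed, x0 = 1) {
  cvs <- vapply(replicate_seeds(seed, replicates), function(s) {
    pooled_cv(simulate_ensemble(x0, sigma, n_chains, T, s))
  }, numeric(1))
  list(median = stats::median(cvs), spread = range(cvs))
}

#' Copying-error sd required to reach a target pooled CV at a given horizon
#'
#' Solves for the `sigma` at which the median pooled CV (over `replicates`
#' seeded ensembles of `n_chains` chains run for `T` generations from
#' `x0 = 1`) equals `cv_target`, by monotone bisection.  Replicate seeds
#' are held fixed across evaluations (common random numbers), which makes
#' the median CV a smooth increasing function of `sigma` and bisection
#' valid.  The solver stops when the achieved CV is within `tol` (relative,
#' default 2%) of the target.
#'
#' The one-generation case has an analytic anchor: at `T = 1` the pooled
#' values are i.i.d. `N(x0, x0^2 sigma^2)`, so the pooled CV tends to
#' `sigma` itself.
#'
#' @param T Horizon in generations, at least 1.
#' @param cv_target Target pooled CV, positive.
#' @param n_chains,replicates,seed,x0 As in [generations_to_cv()].
#' @param tol Relative tolerance on the achieved CV (default 0.02).
#' @param max_iter Bisection iteration cap.
#' @return An `ace_calibration` object with `solved_value` = sigma.
#' @examples
#' \donttest{
#' sigma_for_cv(T = 1, cv_target = 0.1, replicates = 5, seed = 1)
#' }
#' @export
sigma_for_cv <- function(T, cv_target, n_chains = 100, replicates = 25,
                         seed = 1, x0 = 1, tol = 0.02, max_iter = 60) {
  check_scalar(T, "T", lower = 1, integer = TRUE)
  check_scalar(cv_target, "cv_target", lower = 0, strict = TRUE)

  f <- function(sigma)
    median_pooled_cv(sigma, T, n_chains, replicates, seed, x0)
  # initial guess from the small-sigma approximation
  # CV ~ sigma * sqrt((T + 1) / 2), then expand to a bracket
  guess <- cv_target / sqrt((T + 1) / 2)
  lo <- guess / 4; hi <- guess * 4
  f_lo <- f(lo); f_hi <- f(hi)
  expand <- 0
  while (f_lo$median > cv_target && expand < 20) {
    hi <- lo; f_hi <- f_lo
    lo <- lo / 4; f_lo <- f(lo); expand <- expand + 1
  }
  while (f_hi$median < cv_target && expand < 20) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 4; f_hi <- f(hi); expand <- expand + 1
  }
  if (f_lo$median > cv_target || f_hi$median < cv_target)
    stop(sprintf(
      "could not bracket a solution: achievable CV range [%.4g, %.4g] at sigma in [%.3g, %.3g]",
      f_lo$median, f_hi$median, lo, hi), call. = FALSE)

  mid <- NA_real_; f_mid <- NULL
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(f_mid$median - cv_target) <= tol * cv_target) break
    if (f_mid$median < cv_target) lo <- mid else hi <- mid
  }
  new_calibration(solved_value = mid, reached = TRUE, target_cv = cv_target,
                  fixed_parameter = c(T = T), n_chains = n_chains,
                  replicates = replicates, seed = seed,
                  cv_at_solution = f_mid$median, cv_spread = f_mid$spread,
                  solved_for = "sigma")
}

#' Convert a generation count to calendar years
#'
#' @param T Generations, non-negative (vectorised).
#' @param generation_time Years per generation (default 20).
#' @return `T * generation_time`, in years.
#' @examples
#' generations_to_years(200)    # 4000
#' generations_to_years(60000)  # 1.2 million
#' @export
generations_to_years <- function(T, generation_time = 20) {
  vapply(T, check_scalar, numeric(1), name = "T", lower = 0)
  check_scalar(generation_time, "generation_time", lower = 0, strict = TRUE)
  T * generation_time
}

new_calibration <- function(solved_value, reached, target_cv,
                            fixed_parameter, n_chains, replicates, seed,
                            cv_at_solution, cv_spread, solved_for) {
  structure(list(solved_value = solved_value, reached = reached,
                 solved_for = solved_for, target_cv = target_cv,
                 fixed_parameter = fixed_parameter,
                 n_chains = as.integer(n_chains),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 cv_at_solution = cv_at_solution,
                 cv_spread = cv_spread),
            class = "ace_calibration")
}

#' @export
print.ace_calibration <- function(x, ...) {
  fixed <- paste(names(x$fixed_parameter), "=",
                 format(x$fixed_parameter), collapse = ", ")
  if (!x$reached) {
    cat(sprintf(
      "Calibration: target CV %.3g NOT reached (%s; %d chains, %d replicates, seed %d)\n",
      x$target_cv, fixed, x$n_chains, x$replicates, x$seed))
    cat(sprintf("  median pooled CV at the scan limit: %.4g\n",
                x$cv_at_solution))
    return(invisible(x))
  }
  cat(sprintf("Calibration: solved %s = %s for target pooled CV %.3g (%s)\n",
              x$solved_for, format(x$solved_value, digits = 4),
              x$target_cv, fixed))
  cat(sprintf(
    "  %d chains x %d replicates, seed %d; median CV at solution %.4g (replicate range %.4g-%.4g)\n",
    x$n_chains, x$replicates, x$seed, x$cv_at_solution,
    x$cv_spread[1], x$cv_spread[2]))
  if (x$solved_for == "generations")
    cat(sprintf("  implied lifespan at 20 years/generation: %g years\n",
                generations_to_years(x$solved_value)))
  invisible(x)
}
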