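#' Estimate the copying-error standard deviation sigma
#'
#' Under the ACE model the per-event error ratios are i.i.d.
#' `N(1, sigma^2)`, so `sigma` is estimated by the sample standard
#' deviation (n-1 denominator) of the observed produced/target ratios.
#'
#' With `scope = "per-condition"` one estimate is returned per condition.
#' With `scope = "pooled"` two defensible overall summaries exist and both
#' are returned: `sd_all`, the sd of all ratios about the grand mean, and
#' `mean_of_condition_sds`, the arithmetic mean of the per-condition sds.
#' They differ when the conditions have different means (e.g. under a
#' condition-specific bias), and which one an "overall" figure refers to is
#' not always stated in published work, so neither is silently preferred.
#'
#' @param sample Copying-error sample from [compute_copying_errors()], or
#'   any data frame with columns `ratio` and `condition`.
#' @param scope `"per-condition"` or `"pooled"`.
#' @return For `"per-condition"`, a named numeric vector of sds (one per
#'   condition).  For `"pooled"`, a named numeric vector with elements
#'   `sd_all` and `mean_of_condition_sds`.
#' @examples
#' s <- data.frame(ratio = c(1.02, 1.00, 0.98), condition = "larger")
#' estimate_sigma(s)  # 0.02
#' @export
estimate_sigma <- function(sample, scope = c("per-condition", "pooled")) {
  scope <- match.arg(scope)
  if (!all(c("ratio", "condition") %in% names(sample)))
    stop("`sample` needs columns `ratio` and `condition`", call. = FALSE)
  if (any(sample$ratio <= 0))
    stop("copying-error ratios must be positive", call. = FALSE)
  by_cond <- split(sample$ratio, sample$condition)
  if (scope == "per-condition") {
    short <- names(by_cond)[lengths(by_cond) < 2]
    if (length(short) > 0)
      stop("need at least 2 ratios per condition; too few in: ",
           paste(short, collapse = ", "), call. = FALSE)
    vapply(by_cond, stats::sd, numeric(1))
  } else {
    if (length(sample$ratio) < 2)
      stop("need at least 2 ratios", call. = FALSE)
    c(sd_all = stats::sd(sample$ratio),
      mean_of_condition_sds =
        mean(vapply(by_cond, stats::sd, numeric(1))))
  }
}

#' Anderson-Darling test of composite normality
#'
#' Tests whether a sample of copying-error ratios is consistent with a
#' normal distribution whose mean and variance are estimated from the
#' sample (the composite null, Stephens' "case 3").  The A^2 statistic is
#' computed on the probability-transformed order statistics; the p-value
#' uses the small-sample-adjusted statistic
#' `A* = A^2 (1 + 0.75/n + 2.25/n^2)` and Stephens' published approximation
#' for this case.  The computation is delegated to [nortest::ad.test()],
#' which implements exactly this variant; the variant label is carried in
#' the result so reported statistics are comparable across software.
#'
#' @param x Numeric vector of ratios (or any sample), `n >= 8`.
#' @return An object of class `ad_normality`: list with `statistic` (A^2),
#'   `p_value`, `n`, and `variant`.
#' @examples
#' set.seed(1)
#' anderson_darling_normality(rnorm(100, 1, 0.03))
#' @export
anderson_darling_normality <- function(x) {
  if (!is.numeric(x) || anyNA(x))
    stop("`x` must be numeric with no missing values", call. = FALSE)
  if (length(x) < 8)
    stop("the Anderson-Darling test needs at least 8 observations",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("all observations are identical; normality test undefined",
         call. = FALSE)
  fit <- nortest::ad.test(x)
  structure(list(statistic = unname(fit$statistic),
                 p_value = fit$p.value,
                 n = length(x),
                 variant = "composite normality (estimated mean and sd), Stephens case 3, small-sample adjusted"),
            class = "ad_normality")
}

#' @export
print.ad_normality <- function(x, ...) {
  cat(sprintf("Anderson-Darling normality test (n = %d)\n", x$n))
  cat(sprintf("  A = %.4g, p = %.4g\n", x$statistic, x$p_value))
  cat("  variant:", x$variant, "\n")
  invisible(x)
}

#' Final-generation mean and variance across chains
#'
#' The two summary statistics compared against the model's closed-form
#' predictions: the cross-chain mean and sample variance (n-1) of the sizes
#' produced at the last generation.
#'
#' @param x Either a data frame of transmission records or a
#'   `chain_ensemble`.
#' @param condition For records, which condition to summarise.
#' @return Named numeric vector with elements `final_mean` (cm) and
#'   `final_variance` (cm^2).
#' @export
final_chain_stats <- function(x, condition = NULL) {
  if (inherits(x, "chain_ensemble")) {
    finals <- x$sizes[, ncol(x$sizes)]
  } else {
    if (is.null(condition))
      stop("`condition` must be given for record input", call. = FALSE)
    rec <- x[x$condition == condition, , drop = FALSE]
    if (nrow(rec) == 0)
      stop("no records in condition `", condition, "`", call. = FALSE)
    last_gen <- max(rec$generation)
    per_chain <- split(rec, rec$chain_id)
    incomplete <- names(per_chain)[!vapply(
      per_chain, function(ch) last_gen %in% ch$generation, logical(1))]
    if (length(incomplete) > 0)
      stop("chain(s) not reaching generation ", last_gen, ": ",
           paste(incomplete, collapse = ", "), call. = FALSE)
    finals <- vapply(per_chain, function(ch)
      ch$produced_size_cm[ch$generation == last_gen], numeric(1))
  }
  if (length(finals) < 2)
    stop("final variance needs at least 2 chains", call. = FALSE)
  c(final_mean = mean(finals), final_variance = stats::var(finals))
}

# Final-generation means and variances of `reps` simulated experiments,
# vectorised.  Each experiment is `n_chains` chains of `T` generations with
# multiplicative N(1, sigma^2) errors, statistically identical to `reps`
# calls of simulate_ensemble() + final_chain_stats() but generated in one
# block for speed.  Non-positive draws are resampled as in the simulator.
simulate_final_stats <- function(sigma, n_chains, T, x0, reps, seed) {
  set.seed(seed)
  err <- matrix(stats::rnorm(reps * n_chains * T, mean = 1, sd = sigma),
                nrow = T)
  bad <- which(err <= 0)
  while (length(bad) > 0L) {
    err[bad] <- stats::rnorm(length(bad), mean = 1, sd = sigma)
    bad <- bad[err[bad] <= 0]
  }
  finals <- x0 * exp(colSums(log(err)))       # one final size per chain
  finals <- matrix(finals, nrow = n_chains)   # chains x reps
  means <- colMeans(finals)
  vars <- (colSums(finals^2) - n_chains * means^2) / (n_chains - 1)
  list(final_mean = means, final_variance = vars)
}

#' Monte-Carlo empirical p-value for a final-generation statistic
#'
#' Simulates `reps` independent null experiments under the ACE model with
#' the supplied `sigma` and design, and returns the proportion of simulated
#' statistics at least as extreme as the observed one, in the direction of
#' the observed deviation from the model's closed-form prediction
#' (one-sided; ties count as extreme).  The prediction is `x0` for the
#' final mean and `expected_variance(x0, sigma, T)` for the final variance.
#'
#' With the default `direction = "auto"` the test direction is chosen from
#' the sign of `observed - predicted`.  Note that this selection step makes
#' the procedure reject a true null at about twice the nominal rate (either
#' tail can trigger it); pass `direction = "above"` or `"below"` to fix the
#' alternative in advance, in which case the p-value is uniform under the
#' null.
#'
#' @param observed Observed statistic (cm for the mean, cm^2 for the
#'   variance).
#' @param statistic Which statistic: `"final_mean"` or `"final_variance"`.
#' @param sigma Copying-error sd used for the null simulations (typically
#'   the per-condition estimate from [estimate_sigma()]).
#' @param n_chains,T,x0 Experiment design (defaults: 10 chains of 10
#'   generations seeded at 10 cm).
#' @param reps Number of simulated experiments, default 10000.
#' @param seed Seed for the null simulations (default 20121108).
#' @param direction `"auto"` (chosen from the observed deviation, the
#'   default), `"above"` or `"below"`.
#' @return An object of class `empirical_p`: list with `observed`,
#'   `predicted`, `direction` (`"above"` or `"below"`), `p_value`, `reps`,
#'   `seed`, `statistic`.
#' @examples
#' empirical_p_value(10.9, "final_mean", sigma = 0.0269, reps = 1000,
#'                   seed = 7)
#' @export
empirical_p_value <- function(observed,
                              statistic = c("final_mean", "final_variance"),
                              sigma, n_chains = 10, T = 10, x0 = 10,
                              reps = 10000, seed = 20121108,
                              direction = c("auto", "above", "below")) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  check_scalar(observed, "observed")
  check_scalar(sigma, "sigma", lower = 0, strict = TRUE)
  check_scalar(reps, "reps", lower = 100, integer = TRUE)
  check_scalar(n_chains, "n_chains", lower = 2, integer = TRUE)
  check_scalar(T, "T", lower = 1, integer = TRUE)

  predicted <- if (statistic == "final_mean") x0 else
    expected_variance(x0, sigma, T)
  sims <- simulate_final_stats(sigma, n_chains, T, x0, reps, seed)[[statistic]]
  if (direction == "auto")
    direction <- if (observed >= predicted) "above" else "below"
  p <- if (direction == "above") mean(sims >= observed) else
    mean(sims <= observed)
  structure(list(observed = observed, predicted = predicted,
                 direction = direction, p_value = p,
                 reps = as.integer(reps), seed = as.integer(seed),
                 statistic = statistic, sigma = sigma,
                 design = c(n_chains = n_chains, T = T, x0 = x0)),
            class = "empirical_p")
}

#' @export
print.empirical_p <- function(x, ...) {
  cat(sprintf("Empirical p-value for %s (one-sided, %s)\n",
              x$statistic, x$direction))
  cat(sprintf("  observed %.4g vs predicted %.4g; p = %.4g (%d simulations, seed %d)\n",
              x$observed, x$predicted, x$p_value, x$reps, x$seed))
  invisible(x)
}

#' Full analysis of a transmission-chain experiment
#'
#' Runs the complete analysis pipeline on a record table: per-condition and
#' pooled copying-error sd, Anderson-Darling normality per condition, and
#' Monte-Carlo empirical p-values for the final mean and final variance in
#' each condition (each condition's null simulated with its own estimated
#' sigma).
#'
#' @param records Data frame of transmission records.
#' @param reps,seed Passed to [empirical_p_value()].
#' @param x0 Seed size of the experiment (cm).
#' @return A list of class `ace_analysis` with elements `sigma`
#'   (per-condition), `sigma_pooled`, `normality` (per condition),
#'   `final_stats` (per condition), and `p_values` (per condition and
#'   statistic), plus `reps` and `seed`.
#' @export
analyze_experiment <- function(records, reps = 10000, seed = 20121108,
                               x0 = 10) {
  errs <- compute_copying_errors(records, x0 = x0)
  sig <- estimate_sigma(errs, "per-condition")
  conditions <- names(sig)
  normality <- lapply(conditions, function(cond)
    anderson_darling_normality(errs$ratio[errs$condition == cond]))
  names(normality) <- conditions
  T <- max(records$generation)
  n_chains <- length(unique(
    records$chain_id[records$condition == conditions[1]]))
  final_stats <- lapply(conditions, function(cond)
    final_chain_stats(records, cond))
  names(final_stats) <- conditions
  p_values <- lapply(conditions, function(cond) {
    fs <- final_stats[[cond]]
    list(final_mean = empirical_p_value(
           fs[["final_mean"]], "final_mean", sigma = sig[[cond]],
           n_chains = n_chains, T = T, x0 = x0, reps = reps, seed = seed),
         final_variance = empirical_p_value(
           fs[["final_variance"]], "final_variance", sigma = sig[[cond]],
           n_chains = n_chains, T = T, x0 = x0, reps = reps, seed = seed))
  })
  names(p_values) <- conditions
  structure(list(sigma = sig,
                 sigma_pooled = estimate_sigma(errs, "pooled"),
                 normality = normality,
                 final_stats = final_stats,
                 p_values = p_values,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "ace_analysis")
}

#' @export
print.ace_analysis <- function(x, ...) {
  cat("Transmission-chain experiment analysis\n")
  cat("  copying-error sd (sigma) per condition:\n")
  for (cond in names(x$sigma))
    cat(sprintf("    %-8s %.4f\n", cond, x$sigma[[cond]]))
  cat(sprintf("  pooled: sd of all ratios %.4f; mean of condition sds %.4f\n",
              x$sigma_pooled[["sd_all"]],
              x$sigma_pooled[["mean_of_condition_sds"]]))
  cat("  Anderson-Darling normality:\n")
  for (cond in names(x$normality))
    cat(sprintf("    %-8s A = %.2f, p = %.2f\n", cond,
                x$normality[[cond]]$statistic, x$normality[[cond]]$p_value))
  cat(sprintf("  empirical p-values (%d simulations):\n", x$reps))
  for (cond in names(x$p_values)) {
    pv <- x$p_values[[cond]]
    cat(sprintf(
      "    %-8s final mean %.3f cm (p = %.3g, %s); final variance %.3f cm^2 (p = %.3g, %s)\n",
      cond,
      pv$final_mean$observed, pv$final_mean$p_value, pv$final_mean$direction,
      pv$final_variance$observed, pv$final_variance$p_value,
      pv$final_variance$direction))
  }
  invisible(x)
}
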