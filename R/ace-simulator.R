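#' Simulate an ensemble of independent ACE transmission chains
#'
#' Each of `n_chains` chains starts at `x0` and evolves for `T` generations
#' by multiplying the previous value by an independent `N(1, sigma^2)` draw.
#' Draws are consumed chain-major (all `T` generations of chain 1, then
#' chain 2, ...), so a given seed always yields the same ensemble.
#' Non-positive error draws — which would produce a physically meaningless
#' negative size — are rejected and resampled; the number of rejections is
#' recorded in `resample_count`.  At empirically realistic `sigma` a
#' non-positive draw lies more than 10 standard deviations below the mean
#' and in practice never occurs (see [truncated_error_moments()]).
#'
#' @param x0 Starting size (cm), positive.
#' @param sigma Copying-error ratio standard deviation, non-negative.
#' @param n_chains Number of independent chains, at least 1.
#' @param T Number of generations (transmission events), non-negative.
#' @param seed Integer seed for the ensemble's random stream.
#' @return An object of class `chain_ensemble`: a list with elements
#'   `sizes` (an `n_chains` x `(T+1)` matrix of sizes in cm, column `g`
#'   holding generation `g - 1`), `x0`, `sigma`, `n_chains`, `T`, `seed`,
#'   and `resample_count`.
#' @examples
#' ens <- simulate_ensemble(10, 0.0343, n_chains = 10, T = 400, seed = 1)
#' ens
#' @export
simulate_ensemble <- function(x0, sigma, n_chains, T, seed) {
  check_scalar(x0, "x0", lower = 0, strict = TRUE)
  check_scalar(sigma, "sigma", lower = 0)
  check_scalar(n_chains, "n_chains", lower = 1, integer = TRUE)
  check_scalar(T, "T", lower = 0, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)

  set.seed(seed)
  resample_count <- 0L
  if (T > 0) {
    err <- matrix(stats::rnorm(n_chains * T, mean = 1, sd = sigma),
                  nrow = T, ncol = n_chains)
    if (sigma > 0) {
      bad <- which(err <= 0)
      while (length(bad) > 0L) {
        resample_count <- resample_count + length(bad)
        err[bad] <- stats::rnorm(length(bad), mean = 1, sd = sigma)
        bad <- bad[err[bad] <= 0]
      }
    }
    paths <- apply(err, 2L, cumprod)
    if (T == 1L) paths <- matrix(paths, nrow = 1L)
    sizes <- x0 * t(rbind(rep(1, n_chains), paths))
  } else {
    sizes <- matrix(x0, nrow = n_chains, ncol = 1L)
  }
  dimnames(sizes) <- list(NULL, paste0("g", 0:T))
  structure(list(sizes = sizes, x0 = x0, sigma = sigma,
                 n_chains = as.integer(n_chains), T = as.integer(T),
                 seed = as.integer(seed),
                 resample_count = resample_count),
            class = "chain_ensemble")
}

#' @export
print.chain_ensemble <- function(x, ...) {
  cat(sprintf(
    "ACE chain ensemble: %d chains x %d generations (x0 = %g cm, sigma = %g, seed = %d)\n",
    x$n_chains, x$T, x$x0, x$sigma, x$seed))
  fin <- x$sizes[, ncol(x$sizes)]
  cat(sprintf("  final generation: mean %.4g cm, sd %.4g cm, median %.4g cm\n",
              mean(fin), stats::sd(fin), stats::median(fin)))
  if (x$resample_count > 0)
    cat(sprintf("  %d non-positive error draws were resampled\n",
                x$resample_count))
  invisible(x)
}

stopifnot_ensemble <- function(ensemble) {
  if (!inherits(ensemble, "chain_ensemble"))
    stop("expected a `chain_ensemble` (see simulate_ensemble())",
         call. = FALSE)
  invisible(ensemble)
}

#' Cross-chain mean size at each generation
#'
#' @param ensemble A `chain_ensemble` from [simulate_ensemble()].
#' @return Numeric vector of length `T + 1`: the arithmetic mean size (cm)
#'   across chains at generations `0..T`.
#' @export
mean_trajectory <- function(ensemble) {
  stopifnot_ensemble(ensemble)
  colMeans(ensemble$sizes)
}

#' Cross-chain sample variance of size at each generation
#'
#' Uses the n-1 denominator, matching the way between-chain variance is
#' measured in transmission-chain experiments.
#'
#' @param ensemble A `chain_ensemble` with at least 2 chains.
#' @return Numeric vector of length `T + 1`: sample variance (cm^2) across
#'   chains at generations `0..T`.
#' @export
variance_trajectory <- function(ensemble) {
  stopifnot_ensemble(ensemble)
  if (ensemble$n_chains < 2L)
    stop("variance_trajectory needs at least 2 chains", call. = FALSE)
  apply(ensemble$sizes, 2L, stats::var)
}

#' Pooled coefficient of variation of an ensemble
#'
#' Pools every size produced in generations `1..T` by every chain into a
#' single vector and returns its coefficient of variation (sample sd over
#' mean).  This is the summary used to compare the model to archaeological
#' assemblages, which mix artifacts from many lineages and time depths.
#' The seed value (generation 0) is excluded by default since it is an
#' experimental constant, not a produced artifact.
#'
#' @param ensemble A `chain_ensemble` with `T >= 1`.
#' @param include_seed If `TRUE`, generation 0 values enter the pool too.
#' @return The pooled CV (dimensionless).
#' @seealso [generations_to_cv()], [sigma_for_cv()]
#' @export
pooled_cv <- function(ensemble, include_seed = FALSE) {
  stopifnot_ensemble(ensemble)
  if (ensemble$T < 1L)
    stop("pooled_cv needs an ensemble with at least 1 generation",
         call. = FALSE)
  cols <- if (include_seed) seq_len(ensemble$T + 1L) else 2:(ensemble$T + 1L)
  v <- as.vector(ensemble$sizes[, cols, drop = FALSE])
  m <- mean(v)
  if (m <= 0)
    stop("pooled mean is non-positive; CV undefined", call. = FALSE)
  stats::sd(v) / m
}

# Pooled CV at every horizon 1..T in one pass, via cumulative sums over
# generations.  Internal workhorse for the calibration module: computing the
# whole trajectory costs no more than computing the CV at the final horizon.
pooled_cv_trajectory <- function(ensemble) {
  stopifnot_ensemble(ensemble)
  if (ensemble$T < 1L)
    stop("need an ensemble with at least 1 generation", call. = FALSE)
  sz <- ensemble$sizes[, -1L, drop = FALSE]          # drop generation 0
  s1 <- cumsum(unname(colSums(sz)))
  s2 <- cumsum(colSums(sz^2))
  n <- ensemble$n_chains * seq_len(ensemble$T)
  m <- s1 / n
  va <- (s2 - n * m^2) / (n - 1)
  va[n == 1] <- NA_real_
  unname(sqrt(pmax(va, 0)) / m)
}

#' Convert a chain ensemble to a long-format data frame
#'
#' @param x A `chain_ensemble`.
#' @param ... Unused.
#' @return A data frame with columns `chain`, `generation`, `size_cm`.
#' @export
as.data.frame.chain_ensemble <- function(x, ...) {
  data.frame(
    chain = rep(seq_len(x$n_chains), times = x$T + 1L),
    generation = rep(0:x$T, each = x$n_chains),
    size_cm = as.vector(x$sizes))
}

#' Write / read a chain ensemble as long-format CSV
#'
#' The CSV holds columns `chain`, `generation`, `size_cm`; provenance
#' (`x0`, `sigma`, `seed`, `resample_count`) is stored in `#`-prefixed
#' header comments so a round trip restores the full object.
#'
#' @param ensemble A `chain_ensemble`.
#' @param path File path to write to / read from.
#' @return `write_ensemble_csv` returns `path` invisibly;
#'   `read_ensemble_csv` returns a `chain_ensemble`.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot_ensemble(ensemble)
  hdr <- sprintf("# %s=%s",
                 c("x0", "sigma", "seed", "resample_count"),
                 c(format(ensemble$x0, digits = 17),
                   format(ensemble$sigma, digits = 17),
                   ensemble$seed, ensemble$resample_count))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(ensemble), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  lines <- readLines(path, n = 10L)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^# ", "", ln), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  chains <- sort(unique(df$chain))
  gens <- sort(unique(df$generation))
  sizes <- matrix(NA_real_, nrow = length(chains), ncol = length(gens),
                  dimnames = list(NULL, paste0("g", gens)))
  sizes[cbind(match(df$chain, chains), match(df$generation, gens))] <-
    df$size_cm
  structure(list(sizes = sizes,
                 x0 = meta$x0, sigma = meta$sigma,
                 n_chains = length(chains), T = length(gens) - 1L,
                 seed = as.integer(meta$seed),
                 resample_count = as.integer(meta$resample_count)),
            class = "chain_ensemble")
}
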