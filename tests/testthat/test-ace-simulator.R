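test_that("a zero-error ensemble is exactly constant", {
  ens <- simulate_ensemble(10, 0, n_chains = 5, T = 20, seed = 1)
  expect_true(all(ens$sizes == 10))
  expect_equal(dim(ens$sizes), c(5, 21))
  expect_equal(mean_trajectory(ens), rep(10, 21), ignore_attr = TRUE)
  expect_equal(variance_trajectory(ens), rep(0, 21), ignore_attr = TRUE)
  expect_equal(pooled_cv(ens), 0)
})

test_that("ensembles are reproducible from their seed and start at x0", {
  a <- simulate_ensemble(10, 0.05, 50, 30, seed = 99)
  b <- simulate_ensemble(10, 0.05, 50, 30, seed = 99)
  expect_identical(a$sizes, b$sizes)
  expect_true(all(a$sizes[, 1] == 10))
  expect_true(all(a$sizes > 0))
  c <- simulate_ensemble(10, 0.05, 50, 30, seed = 100)
  expect_false(identical(a$sizes, c$sizes))
})

test_that("simulated moments match the closed forms", {
  ens <- simulate_ensemble(10, 0.05, n_chains = 2e4, T = 10, seed = 4)
  finals <- ens$sizes[, 11]
  se_mean <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 10), 3 * se_mean)
  expect_lt(abs(var(finals) - expected_variance(10, 0.05, 10)),
            3 * var_standard_error(finals))
  # trajectories agree entry-wise with the predictions at Monte-Carlo scale
  mt <- mean_trajectory(ens)
  vt <- variance_trajectory(ens)
  for (g in c(3, 6, 10)) {
    se_g <- sd(ens$sizes[, g + 1]) / sqrt(ens$n_chains)
    expect_lt(abs(mt[g + 1] - 10), 4 * se_g)
    expect_lt(abs(vt[g + 1] - expected_variance(10, 0.05, g)),
              4 * var_standard_error(ens$sizes[, g + 1]))
  }
})

test_that("a single-chain ensemble's mean trajectory is the chain itself", {
  ens <- simulate_ensemble(10, 0.05, 1, 10, seed = 2)
  expect_equal(mean_trajectory(ens), ens$sizes[1, ])
  expect_error(variance_trajectory(ens), "2 chains")
})

test_that("most chains drift small while the mean holds (skewed divergence)", {
  ens <- simulate_ensemble(10, 0.05, n_chains = 5e3, T = 400, seed = 11)
  finals <- ens$sizes[, 401]
  expect_lt(median(finals), 10)
  expect_lt(abs(mean(finals) - 10), 4 * sd(finals) / sqrt(length(finals)))
  # log-scale drift: E[log eps] ~ -s^2/2, so log sizes drift down linearly
  mu_log <- mean(log(finals / 10))
  el <- integrate(function(e) log(e) * dnorm(e, 1, 0.05), 0, Inf)$value
  se_log <- sd(log(finals / 10)) / sqrt(length(finals))
  expect_lt(abs(mu_log - 400 * el), 4 * se_log)
  expect_equal(400 * el, -400 * 0.05^2 / 2, tolerance = 0.01)
})

test_that("non-positive draws are never needed at empirical sigma", {
  ens <- simulate_ensemble(10, 0.05, n_chains = 1e4, T = 100, seed = 5)
  expect_identical(ens$resample_count, 0L)
})

test_that("rejection sampling keeps extreme-sigma ensembles positive", {
  ens <- simulate_ensemble(10, 1.5, n_chains = 50, T = 20, seed = 8)
  expect_true(all(ens$sizes > 0))
  expect_gt(ens$resample_count, 0)
})

test_that("pooled CV excludes the seed generation and approaches sigma at T = 1", {
  # at T = 1 the pooled values are i.i.d. N(x0, x0^2 s^2), so CV -> s
  ens <- simulate_ensemble(10, 0.2, n_chains = 1e4, T = 1, seed = 3)
  # se of a normal CV estimate ~ cv/sqrt(2n); allow 3 se
  expect_lt(abs(pooled_cv(ens) - 0.2), 3 * 0.2 / sqrt(2 * 1e4))
  # including the constant seed values dilutes the CV
  expect_lt(pooled_cv(ens, include_seed = TRUE), pooled_cv(ens))
})

test_that("pooled_cv_trajectory agrees with pooled_cv at every horizon", {
  ens <- simulate_ensemble(1, 0.0343, n_chains = 20, T = 30, seed = 6)
  traj <- acemodel:::pooled_cv_trajectory(ens)
  for (h in c(1, 7, 30)) {
    sub <- ens$sizes[, 2:(h + 1), drop = FALSE]
    expect_equal(traj[h], sd(sub) / mean(sub), tolerance = 1e-12)
  }
})

test_that("ensembles round-trip through long-format CSV", {
  ens <- simulate_ensemble(10, 0.0343, 8, 12, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble_csv(ens, path)
  back <- read_ensemble_csv(path)
  expect_equal(back$sizes, ens$sizes, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$x0, ens$x0)
  expect_equal(back$sigma, ens$sigma)
  expect_equal(back$seed, ens$seed)
  df <- as.data.frame(ens)
  expect_equal(nrow(df), 8 * 13)
})
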