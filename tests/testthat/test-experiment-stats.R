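test_that("sigma is the sample sd of the error ratios", {
  s <- data.frame(ratio = c(1.02, 1.00, 0.98), condition = "larger")
  expect_equal(unname(estimate_sigma(s)), 0.02)
  s2 <- data.frame(ratio = rep(1.01, 5), condition = "larger")
  expect_equal(unname(estimate_sigma(s2)), 0)
  expect_error(estimate_sigma(data.frame(ratio = 1, condition = "x")),
               "at least 2")
})

test_that("pooled scope reports both defensible overall summaries", {
  s <- data.frame(ratio = c(1.02, 1.00, 0.98, 1.06, 1.00, 0.94),
                  condition = rep(c("larger", "smaller"), each = 3))
  per <- estimate_sigma(s, "per-condition")
  expect_equal(per, c(larger = 0.02, smaller = 0.06))
  pooled <- estimate_sigma(s, "pooled")
  expect_equal(pooled[["mean_of_condition_sds"]], 0.04)
  expect_equal(pooled[["sd_all"]], sd(s$ratio))
})

test_that("the A-D statistic matches a brute-force evaluation of the sum formula", {
  set.seed(100)
  for (x in list(rnorm(100), rnorm(50, 1, 0.03), rlnorm(80))) {
    res <- anderson_darling_normality(x)
    expect_equal(res$statistic, brute_force_ad_A2(x), tolerance = 1e-10)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
  }
  expect_match(anderson_darling_normality(rnorm(20))$variant, "case 3")
  expect_error(anderson_darling_normality(rnorm(5)), "at least 8")
  expect_error(anderson_darling_normality(rep(1, 20)), "identical")
})

test_that("the A-D test holds its nominal size on normal samples", {
  set.seed(2024)
  p <- replicate(1000, anderson_darling_normality(rnorm(100, 1, 0.03))$p_value)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("final-generation statistics summarise chains correctly", {
  rec <- generate_experiment(sigma = 0, seed = 1)
  expect_equal(final_chain_stats(rec, "larger"),
               c(final_mean = 10, final_variance = 0))
  # from an ensemble
  ens <- simulate_ensemble(10, 0, 5, 10, seed = 1)
  expect_equal(final_chain_stats(ens),
               c(final_mean = 10, final_variance = 0))
  # an incomplete chain is named in the error
  broken <- rec[!(rec$chain_id == "larger_03" & rec$generation == 10), ]
  expect_error(final_chain_stats(broken, "larger"), "larger_03")
  expect_error(final_chain_stats(simulate_ensemble(10, 0, 1, 5, 1)),
               "2 chains")
})

test_that("final variance averaged over replicates matches the closed form", {
  sigma <- 0.05
  set.seed(55)
  seeds <- sample.int(1e6, 400)
  vars <- vapply(seeds, function(s)
    final_chain_stats(simulate_ensemble(10, sigma, 10, 10, s))[["final_variance"]],
    numeric(1))
  se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - expected_variance(10, sigma, 10)), 3 * se)
})

test_that("empirical p-values detect the unreachable and accept the expected", {
  # a 10x inflation of the mean cannot arise in 10 generations at 3% error
  res <- empirical_p_value(100, "final_mean", sigma = 0.0343, reps = 2000,
                           seed = 1)
  expect_equal(res$p_value, 0)
  expect_equal(res$direction, "above")
  # the theoretical variance sits near the center of its null distribution
  v <- expected_variance(10, 0.0343, 10)
  res2 <- empirical_p_value(v, "final_variance", sigma = 0.0343,
                            reps = 10000, seed = 2)
  expect_gt(res2$p_value, 0.2)
  expect_lt(res2$p_value, 0.8)
})

test_that("empirical p-values are monotone in the observed statistic", {
  obs <- c(10.05, 10.2, 10.5, 11)
  p <- vapply(obs, function(o)
    empirical_p_value(o, "final_mean", sigma = 0.0343, reps = 2000,
                      seed = 42)$p_value, numeric(1))
  expect_true(all(diff(p) <= 0))   # further above the prediction => smaller p
  p_below <- vapply(c(9.95, 9.8, 9.5), function(o)
    empirical_p_value(o, "final_mean", sigma = 0.0343, reps = 2000,
                      seed = 42)$p_value, numeric(1))
  expect_true(all(diff(p_below) <= 0))
  # ties count as extreme: p from identical sims is reproducible
  r1 <- empirical_p_value(10.1, "final_mean", sigma = 0.03, reps = 500,
                          seed = 9)
  r2 <- empirical_p_value(10.1, "final_mean", sigma = 0.03, reps = 500,
                          seed = 9)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("with a fixed direction the null p-value is uniform", {
  set.seed(321)
  n_draws <- 100
  obs <- simulate_final_means <- acemodel:::simulate_final_stats(
    0.0343, 10, 10, 10, n_draws, seed = 777)$final_mean
  p <- vapply(seq_len(n_draws), function(i)
    empirical_p_value(obs[i], "final_mean", sigma = 0.0343, reps = 1000,
                      seed = 1000 + i, direction = "above")$p_value,
    numeric(1))
  # Kolmogorov-Smirnov against U(0,1), generous level for MC granularity
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("analyze_experiment runs the full pipeline on a null dataset", {
  rec <- generate_experiment(sigma = 0.0343, seed = 31)
  a <- analyze_experiment(rec, reps = 2000, seed = 17)
  expect_named(a$sigma, c("larger", "smaller"))
  expect_true(all(a$sigma > 0.02 & a$sigma < 0.05))
  expect_gt(a$normality$larger$p_value, 0.001)
  for (cond in c("larger", "smaller")) {
    expect_gt(a$p_values[[cond]]$final_variance$p_value, 0.001)
  }
  expect_output(print(a), "copying-error sd")
})
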