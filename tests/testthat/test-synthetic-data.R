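test_that("the degenerate design reproduces the seed size everywhere", {
  rec <- generate_experiment(sigma = 0, seed = 1)
  expect_equal(nrow(rec), 200)
  expect_true(all(rec$produced_size_cm == 10))
  expect_true(all(rec$target_size_cm == 10))
})

test_that("generation is reproducible and passes the canonical validator", {
  a <- generate_experiment(sigma = 0.0343, seed = 5)
  b <- generate_experiment(sigma = 0.0343, seed = 5)
  expect_identical(a, b)
  expect_silent(validate_records(a))
  expect_equal(sort(unique(a$generation)), 1:10)
  expect_equal(length(unique(a$chain_id)), 20)
  expect_true(all(a$produced_size_cm <= 14.4))
  expect_identical(attr(a, "clip_count"), 0L)
})

test_that("estimate_sigma recovers the generating sigma across replicates", {
  sigma_star <- 0.0343
  bounds <- sigma_star * sqrt(qchisq(c(0.025, 0.975), df = 99) / 99)
  hits <- vapply(1:200, function(r) {
    rec <- generate_experiment(sigma = sigma_star, seed = 5000 + r)
    est <- estimate_sigma(compute_copying_errors(rec))[["larger"]]
    est >= bounds[1] && est <= bounds[2]
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("a condition bias shifts the expected final mean geometrically", {
  # with ratio mean 1 + b the final mean after g generations is
  # x0 (1 + b)^g: +1% over 10 generations moves 10 cm to ~11.046 cm
  b <- 0.01
  expect_equal(10 * (1 + b)^10, 11.0462, tolerance = 1e-4)
  finals <- vapply(1:300, function(r) {
    rec <- generate_biased_pair(sigma = 0.0269, bias_larger = b,
                                bias_smaller = -b, seed = 9000 + r)
    final_chain_stats(rec, "larger")[["final_mean"]]
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 10 * (1 + b)^10), 3 * se)
})

test_that("bias zero on both sides reduces to the unbiased generator", {
  a <- generate_experiment(sigma = 0.03, bias = c(larger = 0, smaller = 0),
                           seed = 44)
  b <- generate_experiment(sigma = 0.03, seed = 44)
  expect_identical(a$produced_size_cm, b$produced_size_cm)
  expect_error(generate_biased_pair(0.03, bias_larger = -0.01,
                                    bias_smaller = -0.02, seed = 1),
               "bias_larger")
  expect_error(generate_biased_pair(0.03, bias_larger = 0.01,
                                    bias_smaller = 0.02, seed = 1),
               "bias_smaller")
})

test_that("a biased dataset is flagged by the final-mean test but not the variance test", {
  flagged <- vapply(1:20, function(r) {
    rec <- generate_biased_pair(sigma = 0.0269, bias_larger = 0.012,
                                bias_smaller = -0.012, seed = 12000 + r)
    a <- analyze_experiment(rec, reps = 2000, seed = 600 + r)
    c(mean_p = a$p_values$larger$final_mean$p_value,
      var_p = a$p_values$larger$final_variance$p_value)
  }, numeric(2))
  expect_gt(mean(flagged["mean_p", ] < 0.05), 0.5)
  expect_gt(mean(flagged["var_p", ] >= 0.05), 0.5)
})

test_that("unbiased synthetic final stats match the model moments over replicates", {
  stats <- vapply(1:300, function(r) {
    rec <- generate_experiment(sigma = 0.05, seed = 20000 + r)
    final_chain_stats(rec, "smaller")
  }, numeric(2))
  se_m <- sd(stats["final_mean", ]) / sqrt(300)
  se_v <- sd(stats["final_variance", ]) / sqrt(300)
  expect_lt(abs(mean(stats["final_mean", ]) - 10), 3 * se_m)
  expect_lt(abs(mean(stats["final_variance", ]) -
                  expected_variance(10, 0.05, 10)), 3 * se_v)
})

test_that("synthetic datasets are written with a provenance sidecar", {
  rec <- generate_experiment(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_synthetic_experiment(rec, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".design.yml")))
  design <- yaml::read_yaml(paste0(path, ".design.yml"))
  expect_equal(design$sigma, 0.0343)
  expect_equal(design$seed, 3)
  back <- read_experiment_csv(path)
  expect_equal(nrow(back), 200)
})
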