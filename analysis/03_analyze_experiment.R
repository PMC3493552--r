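#!/usr/bin/env Rscript

# Full statistical analysis of a transmission-chain experiment table:
# per-condition copying-error sd, Anderson-Darling normality of the error
# ratios, and Monte-Carlo empirical p-values (10,000 simulated experiments
# per test) for the final cross-chain mean and variance against the
# model's closed-form predictions.
#
# Run 02_synthetic_experiment.R first.  To analyze a real dataset instead,
# point `input` at its CSV (read_experiment_csv() takes a column mapping
# if the file uses a different layout).
#
# Writes: results/analysis_null.json, results/analysis_biased.json

library(acemodel)
library(jsonlite)
dir.create("results", showWarnings = FALSE)

analyze_to_json <- function(input, output, reps = 10000, seed = 20121108) {
  rec <- read_experiment_csv(input)
  a <- analyze_experiment(rec, reps = reps, seed = seed)
  print(a)
  flat <- list(
    input = input, reps = a$reps, seed = a$seed,
    sigma = as.list(a$sigma),
    sigma_pooled = as.list(a$sigma_pooled),
    normality = lapply(a$normality, function(x)
      list(A = x$statistic, p = x$p_value, n = x$n, variant = x$variant)),
    final_stats = lapply(a$final_stats, as.list),
    p_values = lapply(a$p_values, function(cond) lapply(cond, function(x)
      list(observed = x$observed, predicted = x$predicted,
           direction = x$direction, p = x$p_value))))
  write_json(flat, output, auto_unbox = TRUE, digits = NA)
  cat("wrote", output, "\n\n")
  invisible(a)
}

cat("=== unbiased (null) dataset ===\n")
null_a <- analyze_to_json("results/synthetic_null.csv",
                          "results/analysis_null.json")

cat("=== biased dataset ===\n")
biased_a <- analyze_to_json("results/synthetic_biased.csv",
                            "results/analysis_biased.json")

cat("In the unbiased data no statistic should be flagged; in the biased\n")
cat("data the final-mean p-values should be extreme in both conditions\n")
cat("while the final variances remain consistent with the model.\n")
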