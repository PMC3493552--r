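# Independent oracles used across test files.

# Brute-force Anderson-Darling A^2 for composite normality: standardize by
# the sample mean and sd (n-1), then evaluate the order-statistic sum
# formula directly.
brute_force_ad_A2 <- function(x) {
  n <- length(x)
  w <- sort((x - mean(x)) / sd(x))
  p <- pnorm(w)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
}

# Hand-rolled record table: a single chain written out explicitly, for
# exercising the validator without the generator.
tiny_records <- function() {
  data.frame(
    condition = "larger",
    chain_id = "larger_01",
    generation = 1:3,
    target_size_cm = c(10, 10.2, 9.9),
    produced_size_cm = c(10.2, 9.9, 10.05))
}

# Monte-Carlo standard error of a sample-variance estimate, from the
# central moments (valid without normality).
var_standard_error <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  sqrt((m4 - m2^2) / n)
}
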