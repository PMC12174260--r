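# Independent reference implementations used as oracles.  These are coded
# directly from the defining formulas, without reusing the package's
# vectorised code paths.

# Brute-force windowed tremor: centered moving mean, then the centered
# moving mean of squared deviations of each sample from its own mean,
# windows truncated at the edges.
tremor_reference <- function(x, window = 5) {
  h <- (window - 1) / 2
  n <- length(x)
  mm <- vapply(seq_len(n), function(t)
    mean(x[max(1, t - h):min(n, t + h)]), numeric(1))
  vapply(seq_len(n), function(t) {
    idx <- max(1, t - h):min(n, t + h)
    mean((x[idx] - mm[idx])^2)
  }, numeric(1))
}

moving_mean_reference <- function(x, window = 5) {
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(t)
    mean(x[max(1, t - h):min(n, t + h)]), numeric(1))
}

# Direct Monte-Carlo estimate of P(sum a X - sum b Y > d), written plainly.
mc_reference <- function(exc, inh, d, n_draws) {
  s <- numeric(n_draws)
  for (a in exc) s <- s + a * runif(n_draws)
  for (b in inh) s <- s - b * runif(n_draws)
  mean(s > d)
}

# Binomial 3-standard-error band check.
within_3se <- function(estimate, p, n) {
  se <- sqrt(max(p * (1 - p), 1e-12) / n)
  abs(estimate - p) <= 3 * se
}
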