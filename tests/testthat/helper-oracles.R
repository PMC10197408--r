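# Independent brute-force oracles for ranks and concentration indices.
# O(n^2) per-observation definitions, no shared code with the package
# implementations.

oracle_rank <- function(y, w) {
  wt <- w / sum(w)
  vapply(seq_along(y), function(i) {
    sum(wt * ((y < y[i]) + 0.5 * (y == y[i])))
  }, numeric(1))
}

# weighted covariance of h with the oracle ranks, via the double sum
# cov = 1/2 * sum_ij wt_i wt_j (h_i - h_j)(R_i - R_j)
oracle_cov_hR <- function(h, y, w) {
  wt <- w / sum(w)
  R <- oracle_rank(y, w)
  s <- 0
  for (i in seq_along(h)) {
    s <- s + sum(wt[i] * wt * (h[i] - h) * (R[i] - R))
  }
  s / 2
}

oracle_standard <- function(h, y, w) {
  2 * oracle_cov_hR(h, y, w) / sum(w / sum(w) * h)
}

oracle_erreygers <- function(h, y, w, bounds = c(0, 1)) {
  8 * oracle_cov_hR(h, y, w) / (bounds[2] - bounds[1])
}

# random binary sample, optionally with income ties
random_binary_sample <- function(n, ties = FALSE) {
  y <- if (ties) sample(1:ceiling(n / 3), n, replace = TRUE) else rnorm(n)
  list(h = rbinom(n, 1, runif(1, 0.15, 0.85)),
       y = y,
       w = runif(n, 0.5, 3))
}

# small complete-covariate microdata for decomposition tests
small_survey <- function(seed = 1, n_countries = 6, persons = 300) {
  cfg <- generator_config(n_countries = n_countries,
                          persons_per_country = persons, seed = seed)
  generate_survey(cfg)
}
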