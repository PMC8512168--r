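# shared fixtures: simple analytic observers and synthetic factor data

# yes/no observer with logistic psychometric function in the tracked value
logistic_observer <- function(theta, sigma = 2, fa = 0.05, gamma = fa,
                              lambda = 0, decreasing = FALSE) {
  function(stimulus_present, value) {
    if (!stimulus_present) return(stats::runif(1) < fa)
    z <- (value - theta) / sigma
    if (decreasing) z <- -z
    p <- gamma + (1 - gamma - lambda) * stats::plogis(z)
    stats::runif(1) < p
  }
}

# deterministic step observer: yes iff the value is detectable, never a
# false alarm
step_observer <- function(theta, decreasing = FALSE) {
  function(stimulus_present, value) {
    if (!stimulus_present) return(FALSE)
    if (decreasing) value <= theta else value >= theta
  }
}

# data from m orthogonal factors with disjoint loading blocks
make_factor_data <- function(n, n_factors = 3, per_factor = 4, loading = 0.8,
                             seed = 1) {
  set.seed(seed)
  p <- n_factors * per_factor
  L <- matrix(0, p, n_factors)
  for (j in seq_len(n_factors))
    L[(j - 1) * per_factor + seq_len(per_factor), j] <- loading
  Fm <- matrix(stats::rnorm(n * n_factors), n, n_factors)
  E <- matrix(stats::rnorm(n * p, 0, sqrt(1 - loading^2)), n, p)
  as.data.frame(Fm %*% t(L) + E)
}
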