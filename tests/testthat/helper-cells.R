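# Shared fixtures, all built in code.

# A weak-prior adaptive cell: belief adapts strongly to recent history.
weak_adaptive_cell <- function(a = 2, b = -1, eta = 0.2) {
  cell_model(belief_prior(c(1, 1), c(1, 1), eta), a = a, b = b)
}

# Stimulus made of isolated flash runs of length 1..k_max, separated by long
# silences, so each run's first trailing silence probes the OSR at that k.
isolated_runs_stimulus <- function(k_max = 10, gap = 15) {
  build_stimulus(flash_runs = seq_len(k_max),
                 silence_runs = rep(gap, k_max))
}

# Beta-posterior predictive by midpoint quadrature: the independent oracle
# for the conjugate pseudo-count form of the predictive.
beta_predictive_quadrature <- function(alpha, beta, n_grid = 1e4) {
  th <- (seq_len(n_grid) - 0.5) / n_grid
  w <- th^(alpha - 1) * (1 - th)^(beta - 1)
  sum(w * th) / sum(w)
}

# Random 0/1 history of length n under a fixed seed.
random_history <- function(n, seed, p = 0.5) {
  withr::with_seed(seed, as.integer(stats::runif(n) < p))
}
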