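test_that("poisson_loglik matches hand values and peaks at rate = count", {
  expect_equal(poisson_loglik(c(0, 0), c(1, 1)), -2)
  expect_equal(poisson_loglik(1, 1), -1)
  expect_error(poisson_loglik(c(1, 2), 1), "length")
  expect_error(poisson_loglik(1, 0), "> 0")
  # for fixed counts the likelihood over unconstrained rates peaks at f = n
  n <- c(2, 5, 1)
  at_n <- poisson_loglik(n, n)
  h <- 1e-4
  for (j in seq_along(n)) {
    up <- n; up[j] <- up[j] + h
    dn <- n; dn[j] <- dn[j] - h
    expect_lt(poisson_loglik(n, up), at_n)
    expect_lt(poisson_loglik(n, dn), at_n)
  }
})

test_that("fixed-model parameters are recovered from synthetic data", {
  stim <- generate_stimulus(n_bins = 10000, seed = 41)
  truth <- cell_model(markov_model(c(0.1, 0.85)), a = 2, b = -1)
  counts <- sample_counts(predict_rates(truth, stim), seed = 42, repeats = 20)
  fit <- fit_cell(stim, counts, "fixed", n_starts = 20, seed = 43)
  th_hat <- fit$params$belief$theta
  expect_lt(abs(th_hat[1] - 0.1), 0.05)
  expect_lt(abs(th_hat[2] - 0.85), 0.05)
  expect_gte(fit$loglik, cell_loglik(truth, stim, counts) - 1)
  expect_gt(fit$correlation, 0.9)
})

test_that("adaptive prior strength is recovered from synthetic data", {
  stim <- generate_stimulus(n_bins = 10000, seed = 51)
  truth <- cell_model(belief_prior(c(2, 3), c(5, 2), 0.2), a = 2, b = -1)
  counts <- sample_counts(predict_rates(truth, stim), seed = 52, repeats = 70)
  fit <- fit_cell(stim, counts, "adaptive", n_starts = 15, seed = 53)
  pr <- fit$params$belief
  expect_lt(abs(log(pr$alpha0[2] + pr$beta0[2]) - log(3 + 2)), 0.5)
  expect_lt(abs(fit$params$a - 2), 0.3)
})

test_that("re-evaluating fitted parameters reproduces the reported loglik", {
  stim <- generate_stimulus(n_bins = 2000, seed = 61)
  truth <- weak_adaptive_cell()
  counts <- sample_counts(predict_rates(truth, stim), seed = 62, repeats = 10)
  fit <- fit_cell(stim, counts, "adaptive", n_starts = 5, seed = 63)
  expect_identical(cell_loglik(fit$params, stim, counts), fit$loglik)
})

test_that("the adaptive family nests the fixed fit on adaptive data", {
  stim <- generate_stimulus(n_bins = 3000, seed = 71)
  truth <- weak_adaptive_cell()
  counts <- sample_counts(predict_rates(truth, stim), seed = 72, repeats = 20)
  fit_ad <- fit_cell(stim, counts, "adaptive", n_starts = 10, seed = 73)
  fit_fx <- fit_cell(stim, counts, "fixed", n_starts = 10, seed = 73)
  expect_gte(fit_ad$loglik, fit_fx$loglik - 1e-3)
  # the reduced symmetric-prior model is itself nested in the full adaptive
  fit_rd <- fit_cell(stim, counts, "adaptive_reduced", n_starts = 10, seed = 74)
  expect_gte(fit_ad$loglik, fit_rd$loglik - 1e-3)
  expect_equal(fit_rd$params$belief$alpha0, fit_rd$params$belief$beta0)
})

test_that("adaptive fits of fixed-model cells land in the strong-prior regime", {
  stim <- generate_stimulus(n_bins = 3000, seed = 301)
  fx <- cell_model(markov_model(c(0.15, 0.8)), a = 2, b = -1)
  counts <- sample_counts(predict_rates(fx, stim), seed = 302, repeats = 20)
  fit <- fit_cell(stim, counts, "adaptive", n_starts = 10, seed = 303)
  pr <- fit$params$belief
  expect_true(all(log(pr$alpha0 + pr$beta0) > 5))
})

test_that("the best loglik is monotone in the number of starts (shared seed)", {
  stim <- generate_stimulus(n_bins = 1500, seed = 81)
  truth <- cell_model(markov_model(c(0.15, 0.8)), a = 1.5, b = -0.5)
  counts <- sample_counts(predict_rates(truth, stim), seed = 82, repeats = 5)
  f3 <- fit_cell(stim, counts, "fixed", n_starts = 3, seed = 99)
  f8 <- fit_cell(stim, counts, "fixed", n_starts = 8, seed = 99)
  expect_equal(f8$start_logliks[1:3], f3$start_logliks)
  expect_gte(f8$loglik, f3$loglik - 1e-9)
})

test_that("compare_fits handles identical inputs and is antisymmetric", {
  stim <- generate_stimulus(n_bins = 2000, seed = 91)
  cells <- list(weak_adaptive_cell(a = 1.5, b = -1), weak_adaptive_cell(a = 2.5, b = 0))
  fits <- lapply(seq_along(cells), function(k) {
    counts <- sample_counts(predict_rates(cells[[k]], stim), seed = 90 + k,
                            repeats = 10)
    fit_cell(stim, counts, "fixed", n_starts = 4, seed = 95 + k)
  })
  same <- compare_fits(fits, fits)
  expect_true(same$degenerate)
  expect_equal(same$statistic, 0)
  expect_true(is.na(same$p_value))
  # antisymmetry of the signed-rank statistic under swapping the fit sets
  fits_b <- lapply(seq_along(cells), function(k) {
    counts <- sample_counts(predict_rates(cells[[k]], stim), seed = 80 + k,
                            repeats = 10)
    fit_cell(stim, counts, "fixed", n_starts = 4, seed = 85 + k)
  })
  ab <- compare_fits(fits, fits_b)
  ba <- compare_fits(fits_b, fits)
  expect_equal(ab$statistic, -ba$statistic)
  expect_true(ab$unreliable)  # fewer than 6 cells
})
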