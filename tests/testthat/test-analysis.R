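# Tree-plots are computed on model rate sequences (noise-free responses)
# where a structural property is asserted, and on sampled counts where the
# statistical pipeline itself is under test.

test_that("tree-plot nodes are exactly conservative", {
  stim <- generate_stimulus(n_bins = 3000, seed = 11)
  resp <- withr::with_seed(12, stats::rpois(3000, 2))
  tree <- history_conditioned_means(resp, stim, n = 6)
  for (d in 2:6) {
    kids <- tree[tree$depth == d, ]
    parents <- tree[tree$depth == d - 1, ]
    agg_n <- tapply(kids$n_obs, substr(kids$history, 2, d), sum)
    agg_m <- tapply(kids$mean * kids$n_obs, substr(kids$history, 2, d), sum)
    idx <- match(parents$history, names(agg_n))
    expect_equal(as.numeric(agg_n[idx]), as.numeric(parents$n_obs))
    expect_equal(as.numeric(agg_m[idx] / agg_n[idx]), parents$mean)
  }
  # constant response: every node mean equals the constant
  tree_c <- history_conditioned_means(rep(1.5, 3000), stim, n = 5)
  expect_true(all(abs(tree_c$mean - 1.5) < 1e-12))
})

test_that("fixed-model responses collapse across histories sharing the last 2 bins", {
  stim <- generate_stimulus(n_bins = 5000, seed = 13)
  cell <- cell_model(markov_model(c(0.2, 0.8)), a = 2, b = -1)
  tree <- history_conditioned_means(predict_rates(cell, stim), stim, n = 8)
  deep <- tree[tree$depth == 8, ]
  key <- substr(deep$history, 7, 8)
  spread <- tapply(deep$mean, key, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("OSR curves have the model-family signatures", {
  stim <- generate_stimulus(n_bins = 30000, seed = 14)
  k_max <- 6
  # fixed: constant for k >= 1
  fx <- cell_model(markov_model(c(0.2, 0.8)), a = 2, b = -1)
  tree_fx <- history_conditioned_means(predict_rates(fx, stim), stim, n = k_max + 1)
  osr_fx <- osr_curve(tree_fx, k_max)
  expect_lt(diff(range(osr_fx$mean)), 1e-12)
  # Markov-2: constant for k >= 2, but k = 1 differs
  m2 <- cell_model(markov_model(c(0.2, 0.7, 0.4, 0.9)), a = 2, b = -1)
  tree_m2 <- history_conditioned_means(predict_rates(m2, stim), stim, n = k_max + 1)
  osr_m2 <- osr_curve(tree_m2, k_max)
  expect_lt(diff(range(osr_m2$mean[-1])), 1e-12)
  expect_gt(abs(osr_m2$mean[1] - osr_m2$mean[2]), 1e-6)
  # adaptive with weak prior: non-decreasing in k
  ad <- weak_adaptive_cell()
  tree_ad <- history_conditioned_means(predict_rates(ad, stim), stim, n = k_max + 1)
  osr_ad <- osr_curve(tree_ad, k_max)
  expect_true(all(diff(osr_ad$mean) > -1e-9))
})

test_that("per-depth correlation separates adaptive data from a fixed fit", {
  stim <- generate_stimulus(n_bins = 5000, seed = 15)
  truth <- weak_adaptive_cell()
  counts <- sample_counts(predict_rates(truth, stim), seed = 16, repeats = 40)
  data_mean <- rowMeans(counts)
  tree_data <- history_conditioned_means(data_mean, stim, n = 8)
  r_self <- tree_correlation_by_depth(tree_data, tree_data)$r
  expect_true(is.na(r_self[1]))          # 2 nodes at depth 1: r undefined
  expect_equal(r_self[2:8], rep(1, 7))
  # affine transforms of node means leave r unchanged
  tree_aff <- tree_data
  tree_aff$mean <- 3 * tree_aff$mean + 2
  r_aff <- tree_correlation_by_depth(tree_data, tree_aff)$r
  expect_equal(r_aff[2:8], rep(1, 7))
  fit_fx <- fit_cell(stim, counts, "fixed", n_starts = 8, seed = 17)
  fit_ad <- fit_cell(stim, counts, "adaptive", n_starts = 8, seed = 17)
  tree_fx <- history_conditioned_means(predict_rates(fit_fx$params, stim), stim, n = 8)
  tree_ad <- history_conditioned_means(predict_rates(fit_ad$params, stim), stim, n = 8)
  r_fx <- tree_correlation_by_depth(tree_data, tree_fx)$r
  r_ad <- tree_correlation_by_depth(tree_data, tree_ad)$r
  # the fixed model loses the deep tree structure; the adaptive model keeps it
  expect_gt(mean(r_ad[4:8]), mean(r_fx[4:8]))
  expect_lt(mean(r_fx[4:8]), 0.8)
  expect_gt(mean(r_ad[4:8]), 0.85)
})

test_that("branching distance vanishes beyond a model's memory", {
  stim <- generate_stimulus(n_bins = 20000, seed = 18)
  m2 <- cell_model(markov_model(c(0.2, 0.7, 0.4, 0.9)), a = 2, b = -1)
  bd_m2 <- branching_distance(
    history_conditioned_means(predict_rates(m2, stim), stim, n = 7))
  # memory = 2 past bins: siblings at depth > 3 share the last 3 symbols
  expect_true(all(bd_m2$distance[bd_m2$depth > 3] < 1e-12))
  expect_gt(bd_m2$distance[bd_m2$depth == 2], 1e-6)
  ad <- weak_adaptive_cell()
  bd_ad <- branching_distance(
    history_conditioned_means(predict_rates(ad, stim), stim, n = 7))
  expect_true(all(bd_ad$distance[bd_ad$depth > 3] > 0))
  # constant tree: zero distance everywhere
  bd_c <- branching_distance(history_conditioned_means(rep(2, 20000), stim, n = 5))
  expect_true(all(bd_c$distance < 1e-12))
})

test_that("refractory QC counts short inter-spike intervals", {
  expect_equal(qc_refractory(c(0, 1, 10)), 0.5)
  expect_equal(qc_refractory(numeric(0)), 0)
  expect_equal(qc_refractory(5), 0)
  expect_error(qc_refractory(c(3, 1, 2)), "sorted")
  # Poisson train at 5 Hz: violation fraction ~ 1 - exp(-5 * 0.002)
  isi <- withr::with_seed(19, stats::rexp(5e4, rate = 5 / 1000))  # ms
  frac <- qc_refractory(cumsum(isi))
  expect_equal(frac, 1 - exp(-5 * 0.002), tolerance = 0.15)
})

test_that("PSTH is a per-repeat mean on a 5 ms grid and scales linearly", {
  one <- compute_psth(list(c(102)), align_ms = 100, window_ms = c(0, 20))
  expect_equal(one$values, c(1, 0, 0, 0))
  reps <- list(c(10, 22), c(11))
  p1 <- compute_psth(reps, 0, c(0, 30))
  p2 <- compute_psth(lapply(reps, function(v) rep(v, each = 2)), 0, c(0, 30))
  expect_equal(p2$values, 2 * p1$values)
  expect_error(compute_psth(list(), 0, c(0, 10)), "nonempty")
  expect_error(compute_psth(reps, 0, c(10, 10)), "window")
})

test_that("OSR detection finds the synthetic post-omission peak", {
  # flat PSTH: no OSR
  flat <- structure(list(t = seq(-120, 295, by = 5), values = rep(1, 84),
                         bin_ms = 5, n_repeats = 10), class = "psth")
  expect_false(detect_osr(flat)$osr)
  # a 5x-baseline peak at 120 ms is an OSR
  vals <- rep(1, 84)
  vals[flat$t >= 115 & flat$t < 130] <- 5
  peaked <- flat; peaked$values <- vals
  res <- detect_osr(peaked)
  expect_true(res$osr)
  expect_true(res$peak_time_ms >= 60 && res$peak_time_ms < 180)
  # the same peak outside the search window is not an OSR
  late <- flat
  late$t <- seq(-120, 395, by = 5); late$values <- rep(1, 104)
  late$values[late$t >= 295 & late$t < 310] <- 5
  expect_false(detect_osr(late)$osr)
})

test_that("the millisecond fixture produces a detectable OSR", {
  stim <- isolated_runs_stimulus(k_max = 8, gap = 12)
  cell <- weak_adaptive_cell(a = 3, b = 0)
  counts <- sample_counts(predict_rates(cell, stim), seed = 20, repeats = 60)
  times <- spike_time_fixture(counts, stim, seed = 21)
  frac <- qc_refractory(times[[1]])
  expect_lt(frac, 0.2)  # sub-bin placement, not a true refractory process
  # align to the omission after the longest run
  x <- stim$x
  osr_bins <- which(x == 0 & c(0L, x[-length(x)]) == 1L)
  t_omit <- (osr_bins[length(osr_bins)] - 1) * stim$bin_ms
  psth <- compute_psth(times, align_ms = t_omit, window_ms = c(-120, 300))
  res <- detect_osr(psth)
  expect_true(res$osr)
  expect_true(res$peak_time_ms >= 60 && res$peak_time_ms < 180)
})

test_that("prior summaries compute ratios, strengths and the strong/weak split", {
  cells <- list(
    cell_model(belief_prior(c(100, 100), c(100, 100), 0.2), 1, 0),
    cell_model(belief_prior(c(1000, 1000), c(1000, 1000), 0.2), 1, 0))
  ps <- prior_summary(cells)
  expect_equal(ps$ratio_1, c(1, 1))
  expect_equal(ps$strength_1, c(200, 2000))
  expect_equal(ps$log_strength_1, log(c(200, 2000)))
  expect_equal(ps$label, c("weak", "strong"))
})

test_that("short- vs long-history correlation separates fixed from adaptive", {
  stim <- generate_stimulus(n_bins = 30000, seed = 22)
  fx <- cell_model(markov_model(c(0.2, 0.8)), a = 2, b = -1)
  r_fx <- short_vs_long_history_correlation(predict_rates(fx, stim), stim)
  expect_equal(r_fx, 1, tolerance = 1e-10)
  ad <- weak_adaptive_cell()
  r_ad <- short_vs_long_history_correlation(predict_rates(ad, stim), stim)
  expect_lt(r_ad, 0.95)
  # stimulus-independent noise: no error, NA or near-zero correlation
  noise <- withr::with_seed(23, stats::rpois(30000, 2))
  r_n <- short_vs_long_history_correlation(noise, stim)
  expect_true(is.na(r_n) || abs(r_n) < 0.5)
})
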