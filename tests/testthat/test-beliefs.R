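test_that("markov_prob reads the correct transition probability and normalises", {
  m1 <- markov_model(c(0.3, 0.9))
  expect_equal(markov_prob(m1, context = 1, x = 0), 0.1)
  expect_equal(markov_prob(m1, context = c(1, 0), x = 1), 0.3)
  for (ctx in 0:1) {
    expect_equal(markov_prob(m1, ctx, 0) + markov_prob(m1, ctx, 1), 1)
  }
  # order 2: contexts ordered (x[t-1], x[t-2]); theta4 is the (1,1) context
  m2 <- markov_model(c(0.1, 0.2, 0.3, 0.8))
  expect_equal(markov_prob(m2, context = c(1, 1), x = 1), 0.8)
  expect_equal(markov_prob(m2, context = c(1, 0), x = 1), 0.3)  # prev=0, prev2=1
  expect_error(markov_prob(m2, context = 1, x = 1), "order")
})

test_that("belief state initialises at the leak fixed point", {
  pr <- belief_prior(1, 1, eta = 0.2)
  st <- init_state(pr)
  expect_equal(st$alpha, c(1, 1))
  expect_equal(st$beta, c(1, 1))
  expect_true(is.na(st$prev_x))
  # predictive at init is the prior mean
  pr2 <- belief_prior(c(2, 6), c(2, 2), eta = 0.3)
  st2 <- init_state(pr2)
  expect_equal(predictive_prob(st2, 0), 0.5)
  expect_equal(predictive_prob(st2, 1), 0.75)
})

test_that("single-step update follows the leaky recursion arithmetic", {
  # eta = 0.2, alpha = 5, alpha0 = 1, active context observes a flash:
  # alpha' = 0.8 * 5 + 0.2 * 1 + 1 = 5.2
  pr <- belief_prior(1, 1, eta = 0.2)
  st <- init_state(pr)
  st$alpha <- c(5, 5)
  st$prev_x <- 0L
  st2 <- update_state(st, 1, pr)
  expect_equal(st2$alpha[1], 5.2)
  expect_equal(st2$alpha[2], 0.8 * 5 + 0.2 * 1)  # inactive context decays only
  expect_equal(st2$prev_x, 1L)
  # eta = 0: plain count increments
  pr0 <- belief_prior(2, 3, eta = 0)
  st <- init_state(pr0)
  for (xx in c(1, 1, 0, 1)) st <- update_state(st, xx, pr0)
  expect_equal(st$alpha, c(2 + 1, 2 + 1))  # transitions 0->1 and 1->1...
  expect_equal(st$beta[2], 3 + 1)          # one 1->0 transition
  # first observation only sets the context
  st <- init_state(pr)
  st1 <- update_state(st, 1, pr)
  expect_equal(st1$alpha, st$alpha)
  expect_equal(st1$prev_x, 1L)
})

test_that("recursive update equals the brute-force discounted sum to 1e-10", {
  for (seed in 1:5) {
    x <- random_history(200, seed)
    for (eta in c(0, 0.2, 0.7)) {
      pr <- belief_prior(c(1.3, 0.7), c(2.1, 1.1), eta = eta)
      st <- init_state(pr)
      for (xx in x) st <- update_state(st, xx, pr)
      for (i in 0:1) for (j in 0:1) {
        bf <- effective_counts_bruteforce(x, eta, i, j)
        rec <- if (j == 1) st$alpha[i + 1] - pr$alpha0[i + 1] else
          st$beta[i + 1] - pr$beta0[i + 1]
        expect_lt(abs(bf - rec), 1e-10)
      }
    }
  }
})

test_that("brute-force counts have the right limits in eta", {
  x <- c(0L, 1L, 1L, 0L, 1L)
  # eta = 0: plain transition counts
  expect_equal(effective_counts_bruteforce(x, 0, 1, 1), 1)
  expect_equal(effective_counts_bruteforce(x, 0, 0, 1), 2)
  expect_equal(effective_counts_bruteforce(x, 0, 1, 0), 1)
  # eta = 1: only the most recent transition survives (here 0 -> 1)
  expect_equal(effective_counts_bruteforce(x, 1, 0, 1), 1)
  expect_equal(effective_counts_bruteforce(x, 1, 1, 1), 0)
})

test_that("predictive equals the beta-posterior mean (quadrature oracle)", {
  pr <- belief_prior(2, 2, eta = 0.2)
  expect_equal(predictive_prob(init_state(pr), 0), 0.5)
  # effective counts n1 = 3, n0 = 1 with unit prior: (3+1)/(3+1+1+1) = 2/3
  pr1 <- belief_prior(1, 1, eta = 0)
  st <- init_state(pr1)
  for (xx in c(0, 1, 1, 1, 0)) st <- update_state(st, xx, pr1)  # ctx 0: 1->, ...
  expect_equal(predictive_prob(st, 1), (2 + 1) / (2 + 1 + 1 + 1))
  # quadrature: posterior-mean of theta under beta(alpha, beta)
  for (ab in list(c(1.5, 3.2), c(0.6, 0.9), c(40, 13))) {
    pr2 <- belief_prior(ab[1], ab[2], eta = 0.2)
    x <- random_history(300, 7)
    p_seq <- predictive_sequence(pr2, x)
    st <- init_state(pr2)
    for (xx in x[1:299]) st <- update_state(st, xx, pr2)
    i <- x[299]
    quad <- beta_predictive_quadrature(st$alpha[i + 1], st$beta[i + 1])
    expect_lt(abs(p_seq[300] - quad), 1e-6)
  }
})

test_that("strong priors collapse the adaptive model onto the fixed model", {
  th <- c(0.25, 0.8)
  for (seed in 1:3) {
    x <- random_history(500, seed + 20)
    scale <- 1e6
    pr <- belief_prior(th * scale, (1 - th) * scale, eta = 0.2)
    p_ad <- predictive_sequence(pr, x)
    iprev <- c(0L, x[-length(x)])
    p_fix <- th[iprev + 1]
    expect_lt(max(abs(p_ad - p_fix)), 1e-3)
  }
})

test_that("dynamic grid filter matches its analytic limits", {
  pr <- belief_prior(c(2, 3), c(4, 1.5), eta = 0.2)
  x <- random_history(400, 3)
  # change_prob = 0: non-leaky conjugate predictive, up to grid error
  p_grid <- dynamic_grid_predict(x, pr, change_prob = 0, grid_size = 400)
  pr0 <- belief_prior(pr$alpha0, pr$beta0, eta = 0)
  p_conj <- predictive_sequence(pr0, x)
  expect_lt(max(abs(p_grid - p_conj)), 5e-3)
  # change_prob = 1: the prior mean at every step
  p_reset <- dynamic_grid_predict(x, pr, change_prob = 1, grid_size = 200)
  iprev <- c(0L, x[-length(x)])
  mu <- (pr$alpha0 / (pr$alpha0 + pr$beta0))[iprev + 1]
  expect_lt(max(abs(p_reset - mu)), 5e-3)
  expect_error(dynamic_grid_predict(x, pr, change_prob = 1.5), "change_prob")
})

test_that("dynamic filter and leaky approximation track each other", {
  stim <- generate_stimulus(n_bins = 2000, seed = 31)
  pr <- belief_prior(c(1, 2), c(3, 2), eta = 0.2)
  p_leaky <- predictive_sequence(pr, stim)
  p_dyn <- dynamic_grid_predict(stim, pr, change_prob = 0.05, grid_size = 200)
  expect_gt(stats::cor(p_leaky[-1], p_dyn[-1]), 0.9)
})

test_that("every belief model emits normalised probabilities in (0, 1)", {
  x <- random_history(300, 12)
  pr <- belief_prior(c(0.3, 5), c(1, 0.2), eta = 0.4)
  p <- predictive_sequence(pr, x)
  expect_true(all(p > 0 & p < 1))
  pd <- dynamic_grid_predict(x, pr, grid_size = 100)
  expect_true(all(pd > 0 & pd < 1))
})
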