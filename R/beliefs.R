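# Internal belief models: what probability does the cell assign to the next
# bin being a flash, given the recent flash/silence history?
#
# Four families are implemented:
#   * fixed first-order Markov (2 transition probabilities, known a priori),
#   * fixed second-order Markov (4 transition probabilities),
#   * adaptive leaky beta-Bernoulli inference: a beta prior per context is
#     combined with exponentially discounted transition counts, so the
#     posterior-predictive is a ratio of leaky pseudo-counts,
#   * a grid-based dynamic-belief reference filter that assumes the
#     transition probabilities can be redrawn from the prior at each step.

#' Fixed Markov internal model
#'
#' Transition probabilities of a binary Markov chain over flash (1) /
#' silence (0) bins.  `theta` of length 2 gives a first-order model with
#' contexts `x[t-1] = 0, 1`; length 4 gives a second-order model with
#' contexts `(x[t-1], x[t-2])` ordered `(0,0), (1,0), (0,1), (1,1)` (i.e.
#' index `1 + x[t-1] + 2 x[t-2]`).
#'
#' @param theta Numeric vector of transition probabilities in (0, 1),
#'   length 2 or 4.
#' @return An object of class `markov_model` with fields `theta` and `order`.
#' @export
markov_model <- function(theta) {
  if (!length(theta) %in% c(2L, 4L)) {
    stop("`theta` must have length 2 (order 1) or 4 (order 2)", call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 1)) {
    stop("all entries of `theta` must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(theta = as.numeric(theta),
                 order = if (length(theta) == 2L) 1L else 2L),
            class = "markov_model")
}

#' Transition probability of a fixed Markov model
#'
#' @param model A [markov_model()].
#' @param context Recent stimulus history as a 0/1 vector with the most
#'   recent bin LAST; must be at least as long as the model order.
#' @param x Outcome (0 or 1) whose probability is requested.
#' @return `p(x | context)`.
#' @export
markov_prob <- function(model, context, x) {
  stopifnot(inherits(model, "markov_model"))
  .check_binary(context, "context")
  .check_binary(x, "x")
  n <- length(context)
  if (n < model$order) {
    stop("`context` must contain at least `order` bins", call. = FALSE)
  }
  idx <- if (model$order == 1L) {
    1L + context[n]
  } else {
    1L + context[n] + 2L * context[n - 1L]
  }
  th <- model$theta[idx]
  if (x == 1) th else 1 - th
}

#' Beta-Bernoulli belief prior with leaky integration
#'
#' Per-context beta prior over the flash transition probabilities, plus the
#' leak `eta` governing exponential forgetting of past transition counts.
#' Context `i` is the value of the previous bin (0 = after silence,
#' 1 = after flash); `alpha0[i+1]`, `beta0[i+1]` set the steady-state
#' pseudo-counts toward which the belief state decays without observations.
#' `alpha0 + beta0` is the strength (confidence) of the prior;
#' `alpha0 / beta0` its mean odds of a flash.
#'
#' @param alpha0,beta0 Positive prior pseudo-counts; scalars are recycled to
#'   the two contexts.
#' @param eta Leak in `[0, 1)`; 0.2 by default (0 recovers exact conjugate
#'   counting with infinite memory).
#' @return An object of class `belief_prior`.
#' @export
belief_prior <- function(alpha0, beta0, eta = 0.2) {
  alpha0 <- rep_len(as.numeric(alpha0), 2L)
  beta0 <- rep_len(as.numeric(beta0), 2L)
  if (any(!is.finite(alpha0)) || any(alpha0 <= 0) ||
      any(!is.finite(beta0)) || any(beta0 <= 0)) {
    stop("`alpha0` and `beta0` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) ||
      eta < 0 || eta >= 1) {
    stop("`eta` must be a single value in [0, 1)", call. = FALSE)
  }
  structure(list(alpha0 = alpha0, beta0 = beta0, eta = eta),
            class = "belief_prior")
}

#' Initial belief state
#'
#' The state holds effective pseudo-counts `alpha = n1~ + alpha0` and
#' `beta = n0~ + beta0` per context.  At initialisation no transitions have
#' been observed, so the state sits at the leak's fixed point
#' `(alpha0, beta0)` and the predictive equals the prior mean.
#'
#' @param prior A [belief_prior()].
#' @return An object of class `belief_state` with fields `alpha`, `beta`
#'   (length-2, contexts 0 and 1) and `prev_x` (`NA` before the first
#'   observation).
#' @export
init_state <- function(prior) {
  stopifnot(inherits(prior, "belief_prior"))
  structure(list(alpha = prior$alpha0, beta = prior$beta0,
                 prev_x = NA_integer_),
            class = "belief_state")
}

#' Single-bin belief update (leaky beta-Bernoulli recursion)
#'
#' Observing `x_t` updates the belief: both contexts decay one step toward
#' their prior (`v <- (1 - eta) v + eta v0`), and the context active at this
#' transition (`i = x[t-1]`) additionally increments `alpha` (if `x_t = 1`)
#' or `beta` (if `x_t = 0`).  The very first observation carries no
#' transition; it only records `prev_x`.
#'
#' @param state A [belief_state()][init_state].
#' @param x_t Observed bin value, 0 or 1.
#' @param prior The [belief_prior()] supplying `alpha0`, `beta0`, `eta`.
#' @return The updated `belief_state`.
#' @export
update_state <- function(state, x_t, prior) {
  stopifnot(inherits(state, "belief_state"), inherits(prior, "belief_prior"))
  if (length(x_t) != 1L || !(x_t %in% c(0, 1))) {
    stop("`x_t` must be 0 or 1", call. = FALSE)
  }
  x_t <- as.integer(x_t)
  if (is.na(state$prev_x)) {
    state$prev_x <- x_t
    return(state)
  }
  eta <- prior$eta
  state$alpha <- (1 - eta) * state$alpha + eta * prior$alpha0
  state$beta <- (1 - eta) * state$beta + eta * prior$beta0
  i <- state$prev_x + 1L
  if (x_t == 1L) state$alpha[i] <- state$alpha[i] + 1 else
    state$beta[i] <- state$beta[i] + 1
  state$prev_x <- x_t
  state
}

#' Posterior-predictive flash probability of a belief state
#'
#' The beta-posterior mean for the given context: with effective counts
#' `n1~`, `n0~` embedded in the state,
#' `p(x = 1 | context i) = (n1~ + alpha0) / (n1~ + n0~ + alpha0 + beta0)`.
#'
#' @param state A [belief_state()][init_state].
#' @param context Previous-bin value, 0 or 1.
#' @return Probability strictly inside (0, 1).
#' @export
predictive_prob <- function(state, context) {
  stopifnot(inherits(state, "belief_state"))
  if (length(context) != 1L || !(context %in% c(0, 1))) {
    stop("`context` must be 0 or 1", call. = FALSE)
  }
  i <- as.integer(context) + 1L
  state$alpha[i] / (state$alpha[i] + state$beta[i])
}

#' Leaky effective transition counts by direct summation
#'
#' Brute-force evaluation of the exponentially discounted transition count
#' `n~_{i -> j} = sum_k (1 - eta)^k [x[T-k] = j][x[T-1-k] = i]` at the end of
#' the supplied history.  This is the closed-form the recursive state update
#' must reproduce; it is exposed as an independent check of the recursion.
#'
#' @param x Stimulus history (0/1 vector or [binned_stimulus()]), length >= 2.
#' @param eta Leak in `[0, 1]`.
#' @param i Context (previous-bin value), 0 or 1.
#' @param j Outcome, 0 or 1.
#' @return Nonnegative effective count.
#' @export
effective_counts_bruteforce <- function(x, eta, i, j) {
  if (inherits(x, "binned_stimulus")) x <- x$x
  .check_binary(x, "x")
  stopifnot(eta >= 0, eta <= 1, i %in% c(0, 1), j %in% c(0, 1))
  tt <- length(x)
  if (tt < 2L) stop("history must contain at least 2 bins", call. = FALSE)
  k <- (tt - 2L):0L  # terms for transitions ending at t' = 2..T
  sum((1 - eta)^(tt - (2:tt)) * (x[2:tt] == j) * (x[1:(tt - 1L)] == i))
}

# Leaky transition-count sequences for all four (i -> j) transitions.
# Element t of each vector is the effective count n~_{i->j} AFTER observing
# x[t] (0 at t = 1, where no transition exists).  Computed with a recursive
# exponential filter, which is exactly the discounted sum above.
leaky_transition_counts <- function(x, eta) {
  tt <- length(x)
  prev <- x[1:(tt - 1L)]
  cur <- x[2:tt]
  filt <- function(i, j) {
    ind <- as.numeric(cur == j & prev == i)
    c(0, as.numeric(stats::filter(ind, 1 - eta, method = "recursive")))
  }
  list(n00 = filt(0, 0), n01 = filt(0, 1),
       n10 = filt(1, 0), n11 = filt(1, 1))
}

# Per-bin ingredients of the adaptive predictive that depend only on the
# stimulus and the leak, not on the prior: the active context i = x[t-1]
# (pre-stimulus bins count as silence) and the effective counts available
# when predicting bin t (i.e. counts through bin t-1).
adaptive_design <- function(x, eta) {
  tt <- length(x)
  counts <- leaky_transition_counts(x, eta)
  iprev <- c(0L, x[1:(tt - 1L)])
  lag <- function(v) c(0, v[1:(tt - 1L)])
  n01p <- lag(counts$n01); n00p <- lag(counts$n00)
  n11p <- lag(counts$n11); n10p <- lag(counts$n10)
  act1 <- iprev == 1L
  list(iprev = iprev,
       n1 = ifelse(act1, n11p, n01p),
       n0 = ifelse(act1, n10p, n00p))
}

#' Predictive flash-probability sequence of the adaptive belief model
#'
#' Runs the leaky beta-Bernoulli model causally along a stimulus and returns
#' `p(x[t] = 1 | x[1..t-1])` for every bin.  Bin 1 has no observed context
#' and is assigned the prior-mean predictive of the silence context
#' (pre-stimulus bins are treated as silent); it is excluded from all
#' likelihoods downstream.
#'
#' @param prior A [belief_prior()].
#' @param stim A [binned_stimulus()] or 0/1 vector, length >= 2.
#' @return Numeric vector of probabilities, one per bin.
#' @export
predictive_sequence <- function(prior, stim) {
  stopifnot(inherits(prior, "belief_prior"))
  stim <- as_binned_stimulus(stim)
  x <- stim$x
  if (length(x) < 2L) stop("stimulus must contain at least 2 bins", call. = FALSE)
  d <- adaptive_design(x, prior$eta)
  a0 <- prior$alpha0[d$iprev + 1L]
  b0 <- prior$beta0[d$iprev + 1L]
  (d$n1 + a0) / (d$n1 + d$n0 + a0 + b0)
}

#' Dynamic-belief reference filter on a probability grid
#'
#' Exact-by-discretisation Bayesian filtering for a model in which the
#' Markov transition probabilities can be redrawn from the prior with
#' probability `change_prob` at every step.  Each context's belief over its
#' transition probability is tracked on an independent grid of `grid_size`
#' midpoints; per bin the belief first mixes with the prior (weight
#' `change_prob`), the predictive is read out, and the active context's
#' belief is then multiplied by the Bernoulli likelihood and renormalised.
#' With `change_prob = 0` this converges to the non-leaky conjugate
#' predictive; with `change_prob = 1` it returns the prior mean at every
#' step.  The defaults `change_prob = 0.01`, `grid_size = 200` are package
#' choices for the reference filter, not experimentally derived values.
#'
#' @param stim A [binned_stimulus()] or 0/1 vector, length >= 2.
#' @param prior A [belief_prior()] (its `eta` is ignored here).
#' @param change_prob Per-bin probability that the transition probabilities
#'   are redrawn from the prior, in `[0, 1]`.
#' @param grid_size Number of grid points per context, `>= 50`.
#' @return Numeric vector of per-bin predictive flash probabilities.
#' @export
dynamic_grid_predict <- function(stim, prior, change_prob = 0.01,
                                 grid_size = 200) {
  stopifnot(inherits(prior, "belief_prior"))
  if (!is.numeric(change_prob) || length(change_prob) != 1L ||
      !is.finite(change_prob) || change_prob < 0 || change_prob > 1) {
    stop("`change_prob` must be a single value in [0, 1]", call. = FALSE)
  }
  if (grid_size < 50) stop("`grid_size` must be >= 50", call. = FALSE)
  stim <- as_binned_stimulus(stim)
  x <- stim$x
  tt <- length(x)
  if (tt < 2L) stop("stimulus must contain at least 2 bins", call. = FALSE)
  th <- (seq_len(grid_size) - 0.5) / grid_size
  w0 <- lapply(1:2, function(i) {
    w <- stats::dbeta(th, prior$alpha0[i], prior$beta0[i])
    w / sum(w)
  })
  w <- w0
  p <- numeric(tt)
  p[1] <- sum(w0[[1]] * th)  # pre-stimulus silence context, prior mean
  for (t in 2:tt) {
    w[[1]] <- (1 - change_prob) * w[[1]] + change_prob * w0[[1]]
    w[[2]] <- (1 - change_prob) * w[[2]] + change_prob * w0[[2]]
    i <- x[t - 1L] + 1L
    p[t] <- sum(w[[i]] * th)
    lik <- if (x[t] == 1L) th else 1 - th
    wi <- w[[i]] * lik
    w[[i]] <- wi / sum(wi)
  }
  p
}
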