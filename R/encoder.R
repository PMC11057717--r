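# Surprise -> firing-rate -> Poisson spike-count encoder.
#
# A cell's rate in bin t is lambda_t = softplus(a * s_t + b), where
# s_t = -log p(x_t | history) is the surprise of the realised bin under the
# cell's internal belief model, a is the gain and b the bias.  Spike counts
# are Poisson with mean lambda_t.

#' Numerically stable softplus
#'
#' `log(1 + exp(x))`, computed without overflow for large `|x|`.
#'
#' @param x Numeric vector.
#' @return Positive numeric vector.
#' @export
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Shannon surprise of a binary outcome
#'
#' `s = -log p(x_t | past)`: `-log(p_x)` when `x_t = 1`, `-log(1 - p_x)`
#' when `x_t = 0`.  Probabilities are clamped to `[1e-12, 1 - 1e-12]` so
#' surprise stays finite at degenerate model probabilities.
#'
#' @param p_x Predictive probability that the bin contains a flash.
#' @param x_t Realised bin value(s), 0 or 1.
#' @return Nonnegative surprise in nats.
#' @export
surprise <- function(p_x, x_t) {
  .check_binary(x_t, "x_t")
  p <- .clamp_prob(p_x)
  ifelse(x_t == 1, -log(p), -log1p(-p))
}

#' Encoder parameters
#'
#' @param a Gain applied to surprise.
#' @param b Bias.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "encoder_params")
}

#' Firing rate from surprise
#'
#' `lambda = softplus(a s + b)`; monotone increasing in `s` when `a > 0`.
#'
#' @param s Surprise value(s), nats.
#' @param enc An [encoder_params()] object (or a list with `a`, `b`).
#' @return Positive rate(s), spikes per bin.
#' @export
encoder_rate <- function(s, enc) {
  softplus(enc$a * s + enc$b)
}

#' Dynamic-belief configuration for a cell
#'
#' Wraps a [belief_prior()] with the change probability and grid size of the
#' grid-based reference filter, for use as a `cell_model` belief.
#'
#' @param prior A [belief_prior()].
#' @param change_prob Per-bin probability of a parameter change.
#' @param grid_size Grid points per context.
#' @return An object of class `dynamic_belief`.
#' @export
dynamic_belief <- function(prior, change_prob = 0.01, grid_size = 200) {
  stopifnot(inherits(prior, "belief_prior"))
  structure(list(prior = prior, change_prob = change_prob,
                 grid_size = grid_size),
            class = "dynamic_belief")
}

#' Full generative model of one cell
#'
#' Combines a belief model (a [markov_model()], a [belief_prior()] — with
#' `reduced = TRUE` marking the symmetric two-parameter prior variant — or a
#' [dynamic_belief()]) with encoder gain and bias.
#'
#' @param belief The internal belief model.
#' @param a,b Encoder gain and bias.
#' @param reduced For a `belief_prior` belief: flag the reduced (alpha0 =
#'   beta0 per context) variant.
#' @return An object of class `cell_model` with a `kind` field in
#'   `{"fixed", "markov2", "adaptive", "adaptive_reduced", "dynamic"}`.
#' @export
cell_model <- function(belief, a, b, reduced = FALSE) {
  stopifnot(is.finite(a), is.finite(b))
  kind <- if (inherits(belief, "markov_model")) {
    if (belief$order == 1L) "fixed" else "markov2"
  } else if (inherits(belief, "belief_prior")) {
    if (isTRUE(reduced)) "adaptive_reduced" else "adaptive"
  } else if (inherits(belief, "dynamic_belief")) {
    "dynamic"
  } else {
    stop("`belief` must be a markov_model, belief_prior or dynamic_belief",
         call. = FALSE)
  }
  structure(list(belief = belief, a = as.numeric(a), b = as.numeric(b),
                 kind = kind),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model kind=%s a=%.3g b=%.3g>\n", x$kind, x$a, x$b))
  invisible(x)
}

# Per-bin predictive flash probabilities of a cell's belief model along a
# stimulus.  Bins before the recording are treated as silences so that every
# context is defined from bin 1; the first two bins are excluded from all
# likelihoods and analyses regardless (warmup).
belief_predictive <- function(belief, stim) {
  stim <- as_binned_stimulus(stim)
  x <- stim$x
  tt <- length(x)
  if (tt < 2L) stop("stimulus must contain at least 2 bins", call. = FALSE)
  if (inherits(belief, "markov_model")) {
    i1 <- c(0L, x[1:(tt - 1L)])
    if (belief$order == 1L) {
      belief$theta[i1 + 1L]
    } else {
      i2 <- c(0L, 0L, x[seq_len(tt - 2L)])
      belief$theta[1L + i1 + 2L * i2]
    }
  } else if (inherits(belief, "belief_prior")) {
    predictive_sequence(belief, stim)
  } else if (inherits(belief, "dynamic_belief")) {
    dynamic_grid_predict(stim, belief$prior, belief$change_prob,
                         belief$grid_size)
  } else {
    stop("unknown belief model", call. = FALSE)
  }
}

# Number of leading bins excluded from likelihoods and rate analyses.  Two
# bins cover the deepest fixed context (Markov-2) and the first adaptive
# transition, so every model kind is scored on identical bins.
.WARMUP_BINS <- 2L

#' Predicted firing-rate sequence of a cell
#'
#' Runs the cell's belief model causally along the stimulus, computes the
#' per-bin surprise of the realised bin, and maps it through the softplus
#' encoder.  The returned vector carries a `warmup` attribute: the number of
#' leading bins (2) that downstream likelihoods and analyses ignore.
#'
#' @param cell A [cell_model()].
#' @param stim A [binned_stimulus()] or 0/1 vector, length >= 2.
#' @return Numeric vector of positive rates (spikes per bin).
#' @export
predict_rates <- function(cell, stim) {
  stopifnot(inherits(cell, "cell_model"))
  stim <- as_binned_stimulus(stim)
  p <- belief_predictive(cell$belief, stim)
  s <- surprise(p, stim$x)
  r <- softplus(cell$a * s + cell$b)
  attr(r, "warmup") <- .WARMUP_BINS
  r
}

#' Sample Poisson spike counts from a rate sequence
#'
#' Independent Poisson draws per bin (and per repeat).
#'
#' @param rates Positive rates, spikes per bin.
#' @param seed Optional integer seed.
#' @param repeats Number of i.i.d. stimulus repeats; with `repeats > 1` a
#'   `length(rates) x repeats` integer matrix is returned.
#' @return Integer vector (or matrix) of spike counts.
#' @export
sample_counts <- function(rates, seed = NULL, repeats = 1) {
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("`rates` must be finite and >= 0", call. = FALSE)
  }
  repeats <- as.integer(repeats)
  stopifnot(repeats >= 1)
  .with_seed(seed, {
    n <- length(rates)
    if (repeats == 1L) {
      stats::rpois(n, rates)
    } else {
      matrix(stats::rpois(n * repeats, rep(rates, repeats)),
             nrow = n, ncol = repeats)
    }
  })
}
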