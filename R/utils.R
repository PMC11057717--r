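# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed (restoring the caller's RNG state),
# or under the current stream when seed is NULL.
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, !is.na(seed))
    withr::with_seed(seed, code)
  }
}

.check_prob <- function(p, name = "p") {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop(sprintf("`%s` must be a single probability strictly inside (0, 1)", name),
         call. = FALSE)
  }
  invisible(p)
}

.check_binary <- function(x, name = "x") {
  if (!all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0 and 1", name), call. = FALSE)
  }
  invisible(x)
}

# Probabilities are clamped away from 0/1 before taking logs so that surprise
# stays finite even at degenerate fitted transition probabilities.
.PROB_EPS <- 1e-12

.clamp_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

# Tiny additive floor applied to rates inside likelihoods so log(rate) is
# always defined; shared by the fitting objective and cell_loglik().
.RATE_FLOOR <- 1e-10
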