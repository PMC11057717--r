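# Maximum-likelihood fitting of cell models under Poisson noise.
#
# The objective is the Poisson log-likelihood L = sum_t n_t log f_t - f_t
# (the n_t! constant omitted), summed over repeats, on raw per-bin counts.
# Parameters are optimised in unconstrained space (logit for transition
# probabilities, log for prior pseudo-counts) with multiple random starts;
# per-start local optimisation uses BFGS with analytic gradients and a
# Nelder-Mead fallback.

#' Poisson log-likelihood of a count sequence under predicted rates
#'
#' `sum_t n_t log(f_t) - f_t`, the Poisson log-likelihood up to the
#' count-factorial constant.
#'
#' @param counts Nonnegative integer counts.
#' @param rates Positive predicted rates, same length.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(counts, rates) {
  if (length(counts) != length(rates)) {
    stop("`counts` and `rates` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("`rates` must be finite and > 0", call. = FALSE)
  }
  if (any(counts < 0)) stop("`counts` must be >= 0", call. = FALSE)
  sum(counts * log(rates) - rates)
}

# Normalise counts input: a vector (one repeat) or bins x repeats matrix.
# Returns list(N = per-bin counts summed over repeats, R = n repeats).
.counts_design <- function(counts, n_bins) {
  if (is.matrix(counts)) {
    if (nrow(counts) != n_bins) {
      stop("`counts` must have one row per stimulus bin", call. = FALSE)
    }
    list(N = rowSums(counts), R = ncol(counts))
  } else {
    if (length(counts) != n_bins) {
      stop("`counts` must have one entry per stimulus bin", call. = FALSE)
    }
    list(N = as.numeric(counts), R = 1L)
  }
}

#' Log-likelihood of a fitted cell model on a recording
#'
#' Evaluates the Poisson log-likelihood (summed over repeats) of a cell
#' model on a stimulus/counts pair, excluding the warmup bins.  This is the
#' exact quantity [fit_cell()] maximises, so re-evaluating a fit's
#' parameters reproduces its reported `loglik`.
#'
#' @param cell A [cell_model()].
#' @param stim A [binned_stimulus()] or 0/1 vector.
#' @param counts Integer vector (single repeat) or bins-by-repeats matrix.
#' @return Scalar log-likelihood.
#' @export
cell_loglik <- function(cell, stim, counts) {
  stim <- as_binned_stimulus(stim)
  cd <- .counts_design(counts, length(stim$x))
  r <- predict_rates(cell, stim)
  valid <- (attr(r, "warmup") + 1L):length(stim$x)
  f <- r[valid] + .RATE_FLOOR
  sum(cd$N[valid] * log(f)) - cd$R * sum(f)
}

# ---- internal optimisation machinery ---------------------------------------

# Per-kind parameter layout (all prior parameters first, then a, b):
#   fixed:            qlogis(theta0), qlogis(theta1)
#   markov2:          qlogis(theta0..theta3)
#   adaptive:         log a0^0, log b0^0, log a0^1, log b0^1
#   adaptive_reduced: log c0, log c1   (alpha0 = beta0 = c per context)
.kind_npar <- function(kind) {
  switch(kind, fixed = 2L, markov2 = 4L, adaptive = 4L,
         adaptive_reduced = 2L,
         stop("unknown model kind: ", kind, call. = FALSE))
}

# Precompute everything that does not depend on the parameters.
.fit_design <- function(stim, counts, kind, eta) {
  x <- stim$x
  tt <- length(x)
  cd <- .counts_design(counts, tt)
  valid <- (.WARMUP_BINS + 1L):tt
  xv <- x[valid]
  des <- list(kind = kind, eta = eta, xv = xv, N = cd$N[valid],
              R = cd$R, nv = length(valid),
              is1 = which(xv == 1L), is0 = which(xv == 0L))
  if (kind %in% c("fixed", "markov2")) {
    i1 <- c(0L, x[1:(tt - 1L)])
    if (kind == "fixed") {
      ctx <- i1[valid]
      des$nctx <- 2L
    } else {
      i2 <- c(0L, 0L, x[seq_len(tt - 2L)])
      ctx <- (i1 + 2L * i2)[valid]
      des$nctx <- 4L
    }
    des$ctx1 <- ctx + 1L
    des$ctx_idx <- lapply(seq_len(des$nctx), function(k) which(des$ctx1 == k))
  } else {
    ad <- adaptive_design(x, eta)
    des$iact <- ad$iprev[valid] + 1L           # 1 = silence ctx, 2 = flash ctx
    des$n1 <- ad$n1[valid]
    des$n0 <- ad$n0[valid]
    des$ctx_idx <- lapply(1:2, function(k) which(des$iact == k))
  }
  des
}

# Negative log-likelihood and its gradient at `par` for a given design,
# sharing all intermediates between the two.
.nll_and_grad <- function(par, des) {
  kind <- des$kind
  np <- .kind_npar(kind)
  a <- par[np + 1L]
  b <- par[np + 2L]
  if (kind %in% c("fixed", "markov2")) {
    th <- stats::plogis(par[seq_len(np)])
    p <- th[des$ctx1]
    D <- NULL
  } else if (kind == "adaptive") {
    # soft box on the log pseudo-counts so exp() cannot overflow
    al <- exp(pmin(pmax(par[c(1L, 3L)], -45), 45))   # contexts 0, 1
    be <- exp(pmin(pmax(par[c(2L, 4L)], -45), 45))
    a_act <- al[des$iact]
    b_act <- be[des$iact]
    D <- des$n1 + des$n0 + a_act + b_act
    p <- (des$n1 + a_act) / D
  } else { # adaptive_reduced
    cc <- exp(pmin(pmax(par[1:2], -45), 45))
    c_act <- cc[des$iact]
    D <- des$n1 + des$n0 + 2 * c_act
    p <- (des$n1 + c_act) / D
  }
  clamped <- p < .PROB_EPS | p > 1 - .PROB_EPS
  if (any(clamped)) p <- .clamp_prob(p)
  s <- numeric(des$nv)
  s[des$is1] <- -log(p[des$is1])
  s[des$is0] <- -log1p(-p[des$is0])
  z <- a * s + b
  f <- softplus(z) + .RATE_FLOOR
  L <- sum(des$N * log(f)) - des$R * sum(f)
  sig <- stats::plogis(z)
  g <- (des$N / f - des$R) * sig
  ga <- sum(g * s)
  gb <- sum(g)
  w <- numeric(des$nv)                    # ds/dp
  w[des$is1] <- -1 / p[des$is1]
  w[des$is0] <- 1 / (1 - p[des$is0])
  gp <- g * a * w
  if (any(clamped)) gp[clamped] <- 0
  if (kind %in% c("fixed", "markov2")) {
    dth <- th * (1 - th)
    gpri <- vapply(seq_len(np), function(k) {
      dth[k] * sum(gp[des$ctx_idx[[k]]])
    }, numeric(1))
  } else if (kind == "adaptive") {
    gpri <- numeric(4L)
    for (k in 1:2) {
      m <- des$ctx_idx[[k]]
      gDm <- gp[m] / D[m]
      gpri[2L * k - 1L] <- al[k] * sum(gDm * (1 - p[m]))
      gpri[2L * k] <- -be[k] * sum(gDm * p[m])
    }
  } else {
    gpri <- numeric(2L)
    for (k in 1:2) {
      m <- des$ctx_idx[[k]]
      gpri[k] <- cc[k] * sum(gp[m] * (1 - 2 * p[m]) / D[m])
    }
  }
  list(value = -L, gradient = -c(gpri, ga, gb))
}

# fn/gr pair over a shared cache: BFGS evaluates fn and gr at the same
# point, so the second call reuses the first call's computation.
.make_objective <- function(des) {
  cache_par <- NULL
  cache_val <- NULL
  eval_at <- function(par) {
    if (is.null(cache_par) || !identical(par, cache_par)) {
      cache_val <<- .nll_and_grad(par, des)
      cache_par <<- par
    }
    cache_val
  }
  list(fn = function(par) eval_at(par)$value,
       gr = function(par) eval_at(par)$gradient)
}

# Draw one random start in unconstrained space (ranges chosen to bracket
# plausible fitted values: theta in (0.05, 0.95), prior pseudo-counts from
# 0.1 to 1e4, gain in (0, 5), bias in (-5, 2)).
.draw_start <- function(kind) {
  np <- .kind_npar(kind)
  pri <- if (kind %in% c("fixed", "markov2")) {
    stats::qlogis(stats::runif(np, 0.05, 0.95))
  } else {
    stats::runif(np, log(0.1), log(1e4))
  }
  c(pri, stats::runif(1, 0, 5), stats::runif(1, -5, 2))
}

.par_to_cell <- function(par, kind, eta) {
  np <- .kind_npar(kind)
  a <- par[np + 1L]
  b <- par[np + 2L]
  belief <- switch(kind,
    fixed = markov_model(stats::plogis(par[1:2])),
    markov2 = markov_model(stats::plogis(par[1:4])),
    adaptive = belief_prior(exp(par[c(1L, 3L)]), exp(par[c(2L, 4L)]), eta),
    adaptive_reduced = belief_prior(exp(par[1:2]), exp(par[1:2]), eta))
  cell_model(belief, a, b, reduced = (kind == "adaptive_reduced"))
}

#' Fit a cell model by multi-start maximum likelihood
#'
#' Maximises the Poisson log-likelihood of the observed spike counts over
#' the cell's belief-model parameters and encoder gain/bias, with
#' `n_starts` random initialisations (50 by default).  The leak `eta` is
#' held fixed (shared across cells).  Model kinds and their free
#' parameters: `"fixed"` (theta0, theta1, a, b), `"markov2"`
#' (theta0..theta3, a, b), `"adaptive"` (alpha0/beta0 per context, a, b),
#' `"adaptive_reduced"` (one symmetric pseudo-count per context, a, b).
#'
#' @param stim A [binned_stimulus()] or 0/1 vector.
#' @param counts Integer vector (one repeat) or bins-by-repeats matrix of
#'   spike counts aligned to the stimulus.
#' @param model_kind One of `"adaptive"`, `"fixed"`, `"markov2"`,
#'   `"adaptive_reduced"`.
#' @param n_starts Number of random starts, `>= 1`.  Starts are drawn
#'   sequentially from the seeded stream, so the first `k` starts coincide
#'   for any two calls sharing a seed.
#' @param seed Optional integer seed for the random starts.
#' @param eta Leak of the adaptive belief model (fixed during fitting).
#' @param depth History depth used for the reported tree-plot correlation.
#' @return An object of class `fit_result`: `model_kind`, `params` (the
#'   fitted [cell_model()]), `loglik`, `n_starts`, `start_logliks`,
#'   `converged`, and `correlation` (Pearson r between model-predicted and
#'   empirical depth-`depth` history-conditioned mean responses).
#' @export
fit_cell <- function(stim, counts,
                     model_kind = c("adaptive", "fixed", "markov2",
                                    "adaptive_reduced"),
                     n_starts = 50, seed = NULL, eta = 0.2, depth = 8) {
  model_kind <- match.arg(model_kind)
  stim <- as_binned_stimulus(stim)
  n_starts <- as.integer(n_starts)
  stopifnot(n_starts >= 1)
  des <- .fit_design(stim, counts, model_kind, eta)
  obj <- .make_objective(des)
  fn <- obj$fn
  gr <- obj$gr

  best <- NULL
  start_lls <- rep(NA_real_, n_starts)
  any_conv <- FALSE
  .with_seed(seed, {
    for (sidx in seq_len(n_starts)) {
      par0 <- .draw_start(model_kind)
      res <- tryCatch(
        stats::optim(par0, fn, gr, method = "BFGS",
                     control = list(maxit = 300)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$value)) {
        res <- tryCatch(
          stats::optim(par0, fn, method = "Nelder-Mead",
                       control = list(maxit = 2000)),
          error = function(e) NULL)
      }
      if (is.null(res) || !is.finite(res$value)) next
      start_lls[sidx] <- -res$value
      if (res$convergence == 0) any_conv <- TRUE
      if (is.null(best) || res$value < best$value) best <- res
    }
  })
  if (is.null(best)) {
    stop("optimisation failed on all ", n_starts, " starts", call. = FALSE)
  }
  if (!any_conv) {
    warning("no start reported convergence; returning best point found",
            call. = FALSE)
  }
  cell <- .par_to_cell(best$par, model_kind, eta)
  ll <- cell_loglik(cell, stim, counts)

  cd <- .counts_design(counts, length(stim$x))
  data_mean <- cd$N / cd$R
  rates <- predict_rates(cell, stim)
  corr <- tryCatch({
    tm <- history_conditioned_means(rates, stim, n = depth)
    td <- history_conditioned_means(data_mean, stim, n = depth)
    .tree_cor_at_depth(td, tm, depth)
  }, error = function(e) NA_real_)

  structure(list(model_kind = model_kind, params = cell, loglik = ll,
                 n_starts = n_starts, start_logliks = start_lls,
                 converged = any_conv, correlation = corr,
                 eta = eta, depth = depth),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: loglik=%.2f, corr=%.3f, %d starts%s>\n",
              x$model_kind, x$loglik,
              ifelse(is.na(x$correlation), NA, x$correlation),
              x$n_starts,
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

# Pearson r between two trees' node means at one depth (observed nodes only).
.tree_cor_at_depth <- function(tree_a, tree_b, depth) {
  a <- tree_a[tree_a$depth == depth, c("history", "mean")]
  b <- tree_b[tree_b$depth == depth, c("history", "mean")]
  m <- merge(a, b, by = "history")
  if (nrow(m) < 3L) return(NA_real_)
  suppressWarnings(stats::cor(m$mean.x, m$mean.y))
}

#' Compare two per-cell fit sets by paired Wilcoxon signed-rank test
#'
#' Pairs each cell's model-vs-data tree correlation under fit set A with the
#' same cell's correlation under fit set B and applies the two-sided
#' Wilcoxon signed-rank test (zero differences discarded, as standard).
#' The reported `statistic` is the sum of signed ranks, positive when A's
#' correlations tend to exceed B's; swapping A and B negates it.
#'
#' @param fits_a,fits_b Lists of [fit_result] objects for the same cells in
#'   the same order, or numeric vectors of per-cell correlations.
#' @return A list of class `fit_comparison`: per-cell correlations and
#'   differences, `statistic`, `p_value`, `n_effective` (nonzero pairs),
#'   `degenerate` (all differences zero) and `unreliable` (fewer than 6
#'   cells).
#' @export
compare_fits <- function(fits_a, fits_b) {
  if (length(fits_a) != length(fits_b) || length(fits_a) == 0) {
    stop("`fits_a` and `fits_b` must be nonempty and the same length",
         call. = FALSE)
  }
  pull <- function(fits) {
    if (is.numeric(fits)) as.numeric(fits) else
      vapply(fits, function(f) f$correlation, numeric(1))
  }
  ca <- pull(fits_a)
  cb <- pull(fits_b)
  ok <- is.finite(ca) & is.finite(cb)
  d <- ca[ok] - cb[ok]
  nz <- d != 0
  if (!any(nz)) {
    statistic <- 0
    p_value <- NA_real_
    degenerate <- TRUE
  } else {
    rk <- rank(abs(d[nz]))
    statistic <- sum(sign(d[nz]) * rk)
    p_value <- suppressWarnings(
      stats::wilcox.test(ca[ok], cb[ok], paired = TRUE)$p.value)
    degenerate <- FALSE
  }
  structure(list(corr_a = ca, corr_b = cb, diff = ca - cb,
                 statistic = statistic, p_value = p_value,
                 n_cells = length(ca), n_effective = sum(nz),
                 degenerate = degenerate,
                 unreliable = sum(ok) < 6L),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf(
    "<fit_comparison: %d cells, signed-rank statistic %.1f, p = %s%s%s>\n",
    x$n_cells, x$statistic,
    format(x$p_value, digits = 3),
    if (x$degenerate) ", degenerate (all ties)" else "",
    if (x$unreliable) ", unreliable (<6 cells)" else ""))
  invisible(x)
}
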