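# Descriptive and diagnostic analyses: history-conditioned tree-plots,
# omitted-stimulus-response (OSR) curves, per-depth model/data correlation,
# branching distance, PSTH, refractory-violation QC, and prior summaries.

#' History-conditioned mean responses (tree-plot)
#'
#' For every terminal stimulus history of length `d <= n`, the mean response
#' over all bins whose preceding `d`-bin window (including the current bin)
#' equals that history.  All depths are computed on the common bin window
#' `t = n .. T`, so the tree is exactly conservative: a parent node's mean is
#' the `n_obs`-weighted average of its two children (which extend the
#' history one bin further into the past), and its `n_obs` is their sum.
#' Unobserved histories are simply absent from the table, never zero-filled.
#'
#' @param response Numeric per-bin response (spike counts, trial-averaged
#'   counts, or model rates); a bins-by-repeats matrix is averaged.
#' @param stim A [binned_stimulus()] or 0/1 vector.
#' @param n Maximum history depth (default 8, giving 256 deepest nodes).
#' @return A data frame of class `tree_plot` with columns `history` (string,
#'   oldest bin first, last character = current bin), `depth`, `ending`
#'   (final symbol), `mean`, `n_obs`; attribute `depth_max`.
#' @export
history_conditioned_means <- function(response, stim, n = 8) {
  stim <- as_binned_stimulus(stim)
  x <- stim$x
  tt <- length(x)
  n <- as.integer(n)
  stopifnot(n >= 1)
  if (tt < n + 1L) stop("stimulus shorter than the requested depth", call. = FALSE)
  if (is.matrix(response)) response <- rowMeans(response)
  if (length(response) != tt) {
    stop("`response` must have one value per stimulus bin", call. = FALSE)
  }
  emb <- stats::embed(x, n)      # row k: bins t = (n + k - 1), col j = x[t - j + 1]
  resp <- response[n:tt]
  out <- vector("list", n)
  for (d in seq_len(n)) {
    code <- as.integer(emb[, seq_len(d), drop = FALSE] %*% 2^(0:(d - 1)))
    cnt <- tabulate(code + 1L, nbins = 2^d)
    sm <- numeric(2^d)
    agg <- rowsum(resp, group = code)
    sm[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    obs <- which(cnt > 0L) - 1L
    out[[d]] <- data.frame(
      history = .code_to_history(obs, d),
      depth = d,
      ending = obs %% 2L,
      mean = sm[obs + 1L] / cnt[obs + 1L],
      n_obs = cnt[obs + 1L],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "depth_max") <- n
  class(res) <- c("tree_plot", "data.frame")
  res
}

# Integer code -> history string; bit 0 (LSB) is the current bin, so the
# string reads oldest-first with the final character being the ending.
.code_to_history <- function(code, d) {
  vapply(code, function(cc) {
    paste(rev(as.integer(intToBits(cc))[seq_len(d)]), collapse = "")
  }, character(1))
}

#' Omitted-stimulus-response curve from a tree-plot
#'
#' The mean response at the first silent bin following `k` consecutive
#' flashes (the top branch of the tree: history `1...10`), for
#' `k = 1 .. k_max`.
#'
#' @param tree A [history_conditioned_means()] tree of depth `>= k_max + 1`.
#' @param k_max Largest flash-run length.
#' @return Data frame with columns `k`, `mean` (NA when the branch was never
#'   observed) and `n_obs`.
#' @export
osr_curve <- function(tree, k_max) {
  stopifnot(inherits(tree, "tree_plot"))
  if (attr(tree, "depth_max") < k_max + 1L) {
    stop("tree depth must be at least k_max + 1", call. = FALSE)
  }
  res <- data.frame(k = seq_len(k_max), mean = NA_real_, n_obs = 0L)
  for (k in seq_len(k_max)) {
    h <- paste0(strrep("1", k), "0")
    row <- tree[tree$history == h & tree$depth == k + 1L, ]
    if (nrow(row) == 1L) {
      res$mean[k] <- row$mean
      res$n_obs[k] <- row$n_obs
    }
  }
  res
}

#' Per-depth correlation between two tree-plots
#'
#' Pearson correlation between the node means of two trees (typically data
#' vs model prediction), computed separately at each depth over the nodes
#' observed in both.
#'
#' @param tree_data,tree_model Two [history_conditioned_means()] trees over
#'   the same stimulus.
#' @return Data frame with columns `depth`, `r` (NA when fewer than 3 common
#'   nodes) and `n_nodes`.
#' @export
tree_correlation_by_depth <- function(tree_data, tree_model) {
  stopifnot(inherits(tree_data, "tree_plot"), inherits(tree_model, "tree_plot"))
  dmax <- min(attr(tree_data, "depth_max"), attr(tree_model, "depth_max"))
  res <- data.frame(depth = seq_len(dmax), r = NA_real_, n_nodes = 0L)
  for (d in seq_len(dmax)) {
    a <- tree_data[tree_data$depth == d, c("history", "mean")]
    b <- tree_model[tree_model$depth == d, c("history", "mean")]
    m <- merge(a, b, by = "history")
    res$n_nodes[d] <- nrow(m)
    if (nrow(m) >= 3L) {
      res$r[d] <- suppressWarnings(stats::cor(m$mean.x, m$mean.y))
    }
  }
  res
}

#' Branching distance of a tree-plot
#'
#' How much sibling branches separate at each depth: for every parent node
#' at depth `d - 1`, its two children at depth `d` extend the history one
#' bin further into the past (prepending a flash or a silence); the
#' branching distance at depth `d` is the mean absolute difference between
#' sibling means, over parents with both children observed.  A model whose
#' rates depend on at most `m` past bins has zero branching distance at all
#' depths `> m + 1`.
#'
#' @param tree A [history_conditioned_means()] tree.
#' @return Data frame with columns `depth` (2 .. depth_max), `distance`, and
#'   `n_pairs`.
#' @export
branching_distance <- function(tree) {
  stopifnot(inherits(tree, "tree_plot"))
  dmax <- attr(tree, "depth_max")
  res <- data.frame(depth = 2:dmax, distance = NA_real_, n_pairs = 0L)
  for (d in 2:dmax) {
    nodes <- tree[tree$depth == d, ]
    if (nrow(nodes) == 0L) next
    first <- substr(nodes$history, 1L, 1L)
    parent <- substr(nodes$history, 2L, d)
    c0 <- nodes[first == "0", c("mean"), drop = FALSE]
    c0$parent <- parent[first == "0"]
    c1 <- nodes[first == "1", c("mean"), drop = FALSE]
    c1$parent <- parent[first == "1"]
    m <- merge(c0, c1, by = "parent")
    res$n_pairs[res$depth == d] <- nrow(m)
    if (nrow(m) > 0L) {
      res$distance[res$depth == d] <- mean(abs(m$mean.y - m$mean.x))
    }
  }
  res
}

#' Fraction of refractory-period violations
#'
#' The fraction of inter-spike intervals shorter than the refractory period
#' (2 ms by default).  Recording-quality selection keeps cells with a
#' fraction below 0.01.
#'
#' @param spike_times_ms Sorted spike times in ms.
#' @param refractory_ms Refractory period in ms.
#' @return Fraction in `[0, 1]` (0 when fewer than 2 spikes).
#' @export
qc_refractory <- function(spike_times_ms, refractory_ms = 2) {
  if (length(spike_times_ms) < 2L) return(0)
  if (is.unsorted(spike_times_ms)) {
    stop("`spike_times_ms` must be sorted", call. = FALSE)
  }
  mean(diff(spike_times_ms) < refractory_ms)
}

#' Peri-stimulus time histogram
#'
#' Mean spike count per time bin across repeats, aligned to an event.
#'
#' @param spike_times_ms List with one sorted numeric vector of spike times
#'   (ms) per repeat.
#' @param align_ms Event time the PSTH is aligned to.
#' @param window_ms Length-2 window `c(lo, hi)` relative to the event.
#' @param bin_ms PSTH bin width (5 ms by default).
#' @return An object of class `psth`: `t` (bin start times relative to the
#'   event), `values` (mean spikes per bin), `bin_ms`, `n_repeats`.
#' @export
compute_psth <- function(spike_times_ms, align_ms, window_ms, bin_ms = 5) {
  if (!is.list(spike_times_ms) || length(spike_times_ms) < 1L) {
    stop("`spike_times_ms` must be a nonempty list of repeats", call. = FALSE)
  }
  if (length(window_ms) != 2L || window_ms[2] <= window_ms[1]) {
    stop("`window_ms` must be c(lo, hi) with hi > lo", call. = FALSE)
  }
  breaks <- seq(window_ms[1], window_ms[2], by = bin_ms)
  if (length(breaks) < 2L) stop("empty PSTH window", call. = FALSE)
  nb <- length(breaks) - 1L
  acc <- numeric(nb)
  for (rep_times in spike_times_ms) {
    rel <- rep_times - align_ms
    rel <- rel[rel >= window_ms[1] & rel < breaks[nb + 1L]]
    if (length(rel)) {
      acc <- acc + tabulate(findInterval(rel, breaks), nbins = nb)
    }
  }
  structure(list(t = breaks[-(nb + 1L)], values = acc / length(spike_times_ms),
                 bin_ms = bin_ms, n_repeats = length(spike_times_ms)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth: %d bins of %g ms over [%g, %g) ms, %d repeats>\n",
              length(x$values), x$bin_ms, x$t[1],
              x$t[length(x$t)] + x$bin_ms, x$n_repeats))
  invisible(x)
}

#' Detect an omitted-stimulus response in a PSTH
#'
#' Declares an OSR present when the PSTH maximum within a post-omission
#' window (60–180 ms by default, centred on the ~120 ms latency at which the
#' next flash was expected) exceeds the baseline — the mean rate over the
#' preceding inter-flash interval — by a configurable factor.
#'
#' @param psth A [compute_psth()] object whose time axis covers at least
#'   `[0, 300]` ms after the omission.
#' @param omitted_flash_ms Time of the omitted flash on the PSTH's time axis.
#' @param window_ms Post-omission search window, relative to the omission.
#' @param baseline_factor Peak-to-baseline ratio required to call an OSR.
#' @param inter_flash_ms Length of the baseline interval preceding the
#'   omission.
#' @return List: `osr` (logical), `peak`, `peak_time_ms` (relative to the
#'   omission), `baseline`.
#' @export
detect_osr <- function(psth, omitted_flash_ms = 0, window_ms = c(60, 180),
                       baseline_factor = 2, inter_flash_ms = 120) {
  stopifnot(inherits(psth, "psth"))
  t_rel <- psth$t - omitted_flash_ms
  if (min(t_rel) > 0 || max(t_rel) + psth$bin_ms < 300) {
    stop("PSTH must cover [0, 300] ms after the omitted flash", call. = FALSE)
  }
  in_win <- t_rel >= window_ms[1] & t_rel < window_ms[2]
  in_base <- t_rel >= -inter_flash_ms & t_rel < 0
  peak <- max(psth$values[in_win])
  peak_time <- t_rel[in_win][which.max(psth$values[in_win])]
  baseline <- if (any(in_base)) mean(psth$values[in_base]) else 0
  osr <- if (baseline > 0) peak > baseline_factor * baseline else peak > 0
  list(osr = osr, peak = peak, peak_time_ms = peak_time, baseline = baseline)
}

#' Summaries of fitted belief priors across cells
#'
#' Per-cell prior mean odds (`alpha0 / beta0`) and prior strength
#' (`alpha0 + beta0`) for both contexts, plus the strong/weak-prior label
#' from thresholding `log(alpha0^1 + beta0^1)` (the flash-context strength).
#'
#' @param fits List of adaptive [fit_result] objects (or [cell_model()]s
#'   with `belief_prior` beliefs).
#' @param log_strength_threshold Split point on the log flash-context
#'   strength (7 by default).
#' @return Data frame with one row per cell: ratios, strengths,
#'   `log_strength_1`, and `label` (`"strong"` / `"weak"`).
#' @export
prior_summary <- function(fits, log_strength_threshold = 7) {
  pri <- lapply(fits, function(f) {
    cell <- if (inherits(f, "fit_result")) f$params else f
    stopifnot(inherits(cell, "cell_model"),
              inherits(cell$belief, "belief_prior"))
    cell$belief
  })
  a0 <- vapply(pri, function(p) p$alpha0[1], numeric(1))
  b0 <- vapply(pri, function(p) p$beta0[1], numeric(1))
  a1 <- vapply(pri, function(p) p$alpha0[2], numeric(1))
  b1 <- vapply(pri, function(p) p$beta0[2], numeric(1))
  ls1 <- log(a1 + b1)
  data.frame(cell = seq_along(pri),
             ratio_0 = a0 / b0, strength_0 = a0 + b0,
             ratio_1 = a1 / b1, strength_1 = a1 + b1,
             log_strength_1 = ls1,
             label = ifelse(ls1 > log_strength_threshold, "strong", "weak"),
             stringsAsFactors = FALSE)
}

#' Correlation of short- vs long-history conditioned responses
#'
#' Pearson correlation between the depth-`long_depth` history-conditioned
#' mean responses and the corresponding depth-`short_depth` means broadcast
#' over their descendants (each deep history inherits the mean of its most
#' recent `short_depth` bins).  r = 1 iff responses depend only on the last
#' `short_depth` bins; values below 1 indicate dependence on stimuli
#' further in the past.
#'
#' @param response Per-bin response vector (or bins-by-repeats matrix).
#' @param stim A [binned_stimulus()] or 0/1 vector.
#' @param short_depth,long_depth History lengths compared (2 and 10 by
#'   default).
#' @return A single correlation, or `NA` when fewer than 3 long histories
#'   were observed or either side is constant.
#' @export
short_vs_long_history_correlation <- function(response, stim,
                                              short_depth = 2,
                                              long_depth = 10) {
  stopifnot(short_depth >= 1, long_depth > short_depth)
  tree <- history_conditioned_means(response, stim, n = long_depth)
  deep <- tree[tree$depth == long_depth, ]
  shallow <- tree[tree$depth == short_depth, ]
  if (nrow(deep) < 3L) return(NA_real_)
  key <- substr(deep$history, long_depth - short_depth + 1L, long_depth)
  m2 <- shallow$mean[match(key, shallow$history)]
  ok <- is.finite(m2) & is.finite(deep$mean)
  if (sum(ok) < 3L) return(NA_real_)
  suppressWarnings(stats::cor(deep$mean[ok], m2[ok]))
}
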