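# Synthetic ground-truth populations and recordings, plus the
# parameter-recovery harness that exercises the whole pipeline
# (sample -> simulate -> fit -> analyse) as a single seeded function.

#' Specification of a synthetic cell population
#'
#' Cells are adaptive-surprise cells with heterogeneous beta priors.  The
#' prior strength `alpha0 + beta0` (per cell, shared mode across contexts)
#' is drawn from a two-mode lognormal mixture — a weak mode near `e^4` and a
#' strong mode near `e^8`, straddling the `log strength = 7` split — while
#' the prior mean odds `alpha0 / beta0` concentrate at unity.  Defaults
#' follow the recording conditions the analyses assume: ~20 minutes of
#' 120 ms bins (1e4 bins) and 70 stimulus repeats.
#'
#' @param n_cells Number of cells.
#' @param strength_meanlog Length-2 vector: mean of `log(alpha0 + beta0)`
#'   for the weak and strong modes.
#' @param strength_sdlog Lognormal sd of the strength within a mode.
#' @param prob_strong Mixture weight of the strong mode.
#' @param ratio_sdlog Lognormal sd of the prior mean odds around 1.
#' @param gain_range,bias_range Uniform ranges for encoder gain and bias.
#' @param eta Leak (shared by all cells).
#' @param repeats Stimulus repeats per cell.
#' @param stimulus_minutes Recording length in minutes.
#' @param bin_ms Bin duration in ms.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 20,
                            strength_meanlog = c(weak = 4, strong = 8),
                            strength_sdlog = 0.5,
                            prob_strong = 0.5,
                            ratio_sdlog = 0.1,
                            gain_range = c(1, 3),
                            bias_range = c(-2, 0),
                            eta = 0.2,
                            repeats = 70,
                            stimulus_minutes = 20,
                            bin_ms = 120) {
  stopifnot(n_cells >= 1, length(strength_meanlog) == 2L,
            strength_meanlog[1] < strength_meanlog[2],
            strength_sdlog > 0, prob_strong >= 0, prob_strong <= 1,
            ratio_sdlog >= 0, repeats >= 1, stimulus_minutes > 0)
  structure(list(n_cells = as.integer(n_cells),
                 strength_meanlog = unname(strength_meanlog),
                 strength_sdlog = strength_sdlog,
                 prob_strong = prob_strong,
                 ratio_sdlog = ratio_sdlog,
                 gain_range = gain_range, bias_range = bias_range,
                 eta = eta, repeats = as.integer(repeats),
                 stimulus_minutes = stimulus_minutes, bin_ms = bin_ms),
            class = "population_spec")
}

#' Sample a synthetic cell population
#'
#' Draws `n_cells` adaptive-surprise [cell_model()]s from a
#' [population_spec()].  Each cell's strength mode (weak/strong) is shared
#' by both contexts; per-context strengths and ratios get independent
#' lognormal jitter.
#'
#' @param spec A [population_spec()].
#' @param seed Optional integer seed.
#' @return List of [cell_model()]s with a `truth` attribute: a data frame of
#'   the generating parameters (gain, bias, per-context alpha0/beta0,
#'   flash-context log strength, and mode label).
#' @export
sample_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  .with_seed(seed, {
    n <- spec$n_cells
    strong <- stats::runif(n) < spec$prob_strong
    cells <- vector("list", n)
    truth <- data.frame(cell = seq_len(n), a = NA_real_, b = NA_real_,
                        alpha0_0 = NA_real_, beta0_0 = NA_real_,
                        alpha0_1 = NA_real_, beta0_1 = NA_real_,
                        log_strength_1 = NA_real_,
                        label = ifelse(strong, "strong", "weak"),
                        stringsAsFactors = FALSE)
    for (k in seq_len(n)) {
      ml <- spec$strength_meanlog[1 + strong[k]]
      s <- exp(stats::rnorm(2, ml, spec$strength_sdlog))      # per context
      rho <- exp(stats::rnorm(2, 0, spec$ratio_sdlog))        # alpha/beta
      alpha0 <- s * rho / (1 + rho)
      beta0 <- s / (1 + rho)
      a <- stats::runif(1, spec$gain_range[1], spec$gain_range[2])
      b <- stats::runif(1, spec$bias_range[1], spec$bias_range[2])
      cells[[k]] <- cell_model(belief_prior(alpha0, beta0, spec$eta), a, b)
      truth[k, c("a", "b")] <- c(a, b)
      truth[k, c("alpha0_0", "beta0_0")] <- c(alpha0[1], beta0[1])
      truth[k, c("alpha0_1", "beta0_1")] <- c(alpha0[2], beta0[2])
      truth$log_strength_1[k] <- log(alpha0[2] + beta0[2])
    }
    attr(cells, "truth") <- truth
    cells
  })
}

#' Simulate a population recording
#'
#' Poisson spike counts for every cell over `repeats` presentations of the
#' same stimulus.
#'
#' @param cells List of [cell_model()]s.
#' @param stim A [binned_stimulus()] or 0/1 vector.
#' @param repeats Number of repeats.
#' @param seed Optional integer seed.
#' @return List with one bins-by-repeats integer count matrix per cell.
#' @export
generate_recording <- function(cells, stim, repeats = 70, seed = NULL) {
  stim <- as_binned_stimulus(stim)
  .with_seed(seed, {
    lapply(cells, function(cell) {
      sample_counts(predict_rates(cell, stim), repeats = repeats)
    })
  })
}

#' Millisecond spike-time fixture from binned counts
#'
#' Expands binned counts into per-repeat millisecond spike times for
#' raster/PSTH testing.  Spikes in the first silent bin after a flash run
#' (the omitted-flash bin) are placed with a Gaussian latency profile around
#' `latency_ms` after the omission, emulating the OSR's timing; spikes in
#' all other bins are placed uniformly.  This sub-bin placement is a
#' generator convenience for timing-level tests — the binned counts are the
#' model-faithful observable.
#'
#' @param counts Bins-by-repeats count matrix (or vector for one repeat).
#' @param stim The [binned_stimulus()] the counts were generated from.
#' @param latency_ms,sd_ms OSR latency profile parameters.
#' @param seed Optional integer seed.
#' @return List with one sorted numeric vector of spike times (ms) per
#'   repeat.
#' @export
spike_time_fixture <- function(counts, stim, latency_ms = 120, sd_ms = 25,
                               seed = NULL) {
  stim <- as_binned_stimulus(stim)
  x <- stim$x
  bw <- stim$bin_ms
  if (!is.matrix(counts)) counts <- matrix(counts, ncol = 1L)
  stopifnot(nrow(counts) == length(x))
  osr_bin <- c(FALSE, x[-1] == 0L & x[-length(x)] == 1L)
  .with_seed(seed, {
    lapply(seq_len(ncol(counts)), function(r) {
      times <- numeric(0)
      for (t in which(counts[, r] > 0L)) {
        n <- counts[t, r]
        t0 <- (t - 1) * bw
        if (osr_bin[t]) {
          tm <- t0 + stats::rnorm(n, latency_ms, sd_ms)
          tm <- pmin(pmax(tm, t0), t0 + 2 * bw - 1e-6)
        } else {
          tm <- t0 + stats::runif(n, 0, bw)
        }
        times <- c(times, tm)
      }
      sort(times)
    })
  })
}

#' Parameter-recovery experiment
#'
#' The pipeline's acceptance surface: sample a population, simulate its
#' recording on a fresh stimulus, fit the requested model kinds to every
#' cell, and report recovery of the generative parameters together with the
#' adaptive-vs-fixed model comparison.  The whole experiment is a
#' deterministic function of `(spec, seed)`.
#'
#' @param spec A [population_spec()].
#' @param n_starts Random starts per fit.
#' @param seed Integer seed driving stimulus, population, spiking and fits.
#' @param model_kinds Model kinds to fit (the first adaptive kind supplies
#'   the recovered priors; `"fixed"` supplies the comparison baseline).
#' @param depth Tree depth for the reported correlations.
#' @return An object of class `recovery_report`: `cells` (per-cell truth,
#'   estimates, errors, labels and correlations), `summary` (median
#'   absolute log-strength error, strong/weak label agreement, fraction of
#'   weak-prior cells better fit by the adaptive model, Wilcoxon p-values),
#'   `comparison` (the [compare_fits()] object over all cells), `fits`,
#'   `stimulus`, and `spec`.
#' @export
recovery_experiment <- function(spec = population_spec(), n_starts = 50,
                                seed = 1,
                                model_kinds = c("adaptive", "fixed"),
                                depth = 8) {
  stopifnot(inherits(spec, "population_spec"),
            "adaptive" %in% model_kinds)
  n_bins <- round(spec$stimulus_minutes * 60 * 1000 / spec$bin_ms)
  .with_seed(seed, {
    stim <- generate_stimulus(n_bins = n_bins, bin_ms = spec$bin_ms)
    cells <- sample_population(spec)
    truth <- attr(cells, "truth")
    recs <- generate_recording(cells, stim, repeats = spec$repeats)

    fits <- lapply(model_kinds, function(kind) {
      lapply(seq_along(cells), function(k) {
        tryCatch(
          fit_cell(stim, recs[[k]], model_kind = kind,
                   n_starts = n_starts, eta = spec$eta, depth = depth),
          error = function(e) {
            warning(sprintf("fit failed for cell %d (%s): %s",
                            k, kind, conditionMessage(e)), call. = FALSE)
            NULL
          })
      })
    })
    names(fits) <- model_kinds

    ad <- fits[["adaptive"]]
    ok <- !vapply(ad, is.null, logical(1))
    est_ls1 <- rep(NA_real_, length(cells))
    est_label <- rep(NA_character_, length(cells))
    corr_ad <- rep(NA_real_, length(cells))
    for (k in which(ok)) {
      pr <- ad[[k]]$params$belief
      est_ls1[k] <- log(pr$alpha0[2] + pr$beta0[2])
      est_label[k] <- if (est_ls1[k] > 7) "strong" else "weak"
      corr_ad[k] <- ad[[k]]$correlation
    }
    per_cell <- cbind(truth,
                      est_log_strength_1 = est_ls1,
                      log_strength_err = est_ls1 - truth$log_strength_1,
                      est_label = est_label,
                      corr_adaptive = corr_ad,
                      fit_failed = !ok)

    comparison <- NULL
    if ("fixed" %in% model_kinds) {
      fx <- fits[["fixed"]]
      okb <- ok & !vapply(fx, is.null, logical(1))
      per_cell$corr_fixed <- NA_real_
      per_cell$corr_fixed[okb] <-
        vapply(fx[okb], function(f) f$correlation, numeric(1))
      if (sum(okb) >= 2L) comparison <- compare_fits(ad[okb], fx[okb])
    }

    weak <- per_cell$label == "weak" & !per_cell$fit_failed
    frac_ad_better_weak <- if (any(weak) && "corr_fixed" %in% names(per_cell)) {
      mean(per_cell$corr_adaptive[weak] >= per_cell$corr_fixed[weak],
           na.rm = TRUE)
    } else NA_real_
    p_weak <- if (sum(weak, na.rm = TRUE) >= 2L &&
                  "fixed" %in% model_kinds) {
      compare_fits(ad[weak], fits[["fixed"]][weak])$p_value
    } else NA_real_

    summary <- list(
      n_cells = length(cells),
      n_fit_failed = sum(!ok),
      median_abs_log_strength_err = stats::median(abs(per_cell$log_strength_err),
                                                  na.rm = TRUE),
      label_agreement = mean(per_cell$est_label == per_cell$label,
                             na.rm = TRUE),
      frac_adaptive_better_weak = frac_ad_better_weak,
      wilcoxon_p_weak = p_weak,
      wilcoxon_p_all = if (!is.null(comparison)) comparison$p_value else NA_real_)

    structure(list(cells = per_cell, summary = summary,
                   comparison = comparison, fits = fits,
                   stimulus = stim, spec = spec, seed = seed),
              class = "recovery_report")
  })
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<recovery_report: %d cells (%d failed)\n",
           "  median |log-strength error| = %.3f\n",
           "  strong/weak label agreement = %.2f\n",
           "  adaptive >= fixed on weak-prior cells: %.2f (Wilcoxon p = %s)>\n"),
    s$n_cells, s$n_fit_failed, s$median_abs_log_strength_err,
    s$label_agreement, s$frac_adaptive_better_weak,
    format(s$wilcoxon_p_weak, digits = 3)))
  invisible(x)
}
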