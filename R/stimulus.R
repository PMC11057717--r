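# Stochastic flash-sequence stimulus: run-length generators on a 120 ms grid.
#
# The stimulus alternates runs of full-field flashes (one flash per 120 ms
# bin) and runs of silent bins.  Flash-run lengths follow a shifted negative
# binomial whose size parameter is chosen to hold the mean run length fixed
# (7 flashes by default) as the dispersion parameter p varies; silence-run
# lengths follow a geometric distribution on {1, 2, ...} (mean 9 by default).

#' Negative-binomial size parameter matching a target mean run length
#'
#' Flash runs are modelled as `1 + NB(r, p)` (number-of-failures
#' parameterisation, so the run length is supported on \{1, 2, ...\}).  The
#' mean run length is then `1 + r (1 - p) / p`; this function solves for the
#' size `r` that attains a given target mean, so that the mean number of
#' consecutive flashes stays constant while `p` controls how tightly run
#' lengths cluster around it.
#'
#' @param p NB probability parameter, strictly in (0, 1).
#' @param target_mean Desired mean run length, `>= 1`.
#' @return The size parameter `r >= 0` (0 when `target_mean == 1`, in which
#'   case every run has length exactly 1).
#' @examples
#' nb_size_for_mean(0.5, 7)   # 6
#' @export
nb_size_for_mean <- function(p, target_mean) {
  .check_prob(p, "p")
  if (!is.numeric(target_mean) || length(target_mean) != 1L ||
      !is.finite(target_mean) || target_mean < 1) {
    stop("`target_mean` must be a single finite number >= 1", call. = FALSE)
  }
  (target_mean - 1) * p / (1 - p)
}

#' Run-length distribution parameters
#'
#' Describes the distribution of the number of consecutive flashes
#' (`kind = "flash"`: shifted negative binomial, with the size parameter
#' derived via [nb_size_for_mean()]) or consecutive silent bins
#' (`kind = "silence"`: geometric on \{1, 2, ...\} with success probability
#' `1 / mean_run`).
#'
#' @param kind `"flash"` or `"silence"`.
#' @param p NB probability parameter (flash runs only; ignored for silences).
#' @param mean_run Target mean run length (bins), `>= 1`.
#' @return An object of class `run_length_params`.
#' @export
run_length_params <- function(kind = c("flash", "silence"), p = 0.8, mean_run = 7) {
  kind <- match.arg(kind)
  if (!is.numeric(mean_run) || length(mean_run) != 1L ||
      !is.finite(mean_run) || mean_run < 1) {
    stop("`mean_run` must be a single finite number >= 1", call. = FALSE)
  }
  r <- NULL
  if (kind == "flash") {
    .check_prob(p, "p")
    r <- nb_size_for_mean(p, mean_run)
  }
  structure(list(kind = kind, p = p, mean_run = mean_run, r = r),
            class = "run_length_params")
}

#' Sample run lengths
#'
#' Draws run lengths from the distribution described by `params`.  All runs
#' are `>= 1` (a run of zero flashes or zero silences is meaningless).
#'
#' @param params A [run_length_params()] object.
#' @param n_runs Number of runs to draw (`>= 1`).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Integer vector of `n_runs` run lengths.
#' @export
sample_runs <- function(params, n_runs, seed = NULL) {
  stopifnot(inherits(params, "run_length_params"))
  if (!is.numeric(n_runs) || length(n_runs) != 1L || is.na(n_runs) || n_runs < 1) {
    stop("`n_runs` must be a single integer >= 1", call. = FALSE)
  }
  n_runs <- as.integer(n_runs)
  .with_seed(seed, {
    if (params$kind == "flash") {
      if (params$r == 0) {
        rep.int(1L, n_runs)
      } else {
        stats::rnbinom(n_runs, size = params$r, prob = params$p) + 1L
      }
    } else {
      stats::rgeom(n_runs, prob = 1 / params$mean_run) + 1L
    }
  })
}

#' Binned binary stimulus
#'
#' A flash/silence sequence on a fixed time grid: `x[t] = 1` if the 120 ms
#' bin `t` contains a flash, 0 otherwise.
#'
#' @param x Vector of 0/1 values.
#' @param bin_ms Bin duration in milliseconds (120 for all standard analyses).
#' @return An object of class `binned_stimulus` with fields `x` and `bin_ms`.
#' @export
binned_stimulus <- function(x, bin_ms = 120) {
  .check_binary(x, "x")
  stopifnot(is.numeric(bin_ms), length(bin_ms) == 1L, bin_ms > 0)
  structure(list(x = as.integer(x), bin_ms = bin_ms), class = "binned_stimulus")
}

#' @export
length.binned_stimulus <- function(x) length(x$x)

#' @export
print.binned_stimulus <- function(x, ...) {
  cat(sprintf("<binned_stimulus: %d bins of %g ms, %d flashes>\n",
              length(x$x), x$bin_ms, sum(x$x)))
  invisible(x)
}

# Accept either a binned_stimulus or a raw 0/1 vector.
as_binned_stimulus <- function(stim, bin_ms = 120) {
  if (inherits(stim, "binned_stimulus")) stim else binned_stimulus(stim, bin_ms)
}

#' Interleave flash and silence runs into a binary stimulus
#'
#' Builds the binary bin sequence that alternates blocks of 1s (flash runs)
#' and 0s (silence runs), beginning with the first flash run.
#'
#' @param flash_runs,silence_runs Vectors of run lengths (`>= 1`).  The
#'   silence vector may contain one run fewer than the flash vector (when the
#'   stimulus ends on a flash run) or equally many.
#' @param bin_ms Bin duration in ms.
#' @return A [binned_stimulus()].
#' @examples
#' build_stimulus(c(3), c(2))$x   # 1 1 1 0 0
#' @export
build_stimulus <- function(flash_runs, silence_runs, bin_ms = 120) {
  if (length(flash_runs) == 0 || length(silence_runs) == 0) {
    stop("both run lists must be nonempty", call. = FALSE)
  }
  if (any(flash_runs < 1) || any(silence_runs < 1)) {
    stop("every run length must be >= 1", call. = FALSE)
  }
  nf <- length(flash_runs)
  ns <- length(silence_runs)
  if (!(ns %in% c(nf, nf - 1L))) {
    stop("`silence_runs` must have the same length as `flash_runs`, or one fewer",
         call. = FALSE)
  }
  lens <- integer(nf + ns)
  lens[seq(1L, by = 2L, length.out = nf)] <- as.integer(flash_runs)
  if (ns > 0) lens[seq(2L, by = 2L, length.out = ns)] <- as.integer(silence_runs)
  vals <- rep_len(c(1L, 0L), nf + ns)
  binned_stimulus(rep(vals, times = lens), bin_ms = bin_ms)
}

#' Extract alternating run lengths from a stimulus
#'
#' Inverse of [build_stimulus()]: returns the flash and silence run lengths
#' of a binary stimulus.
#'
#' @param stim A [binned_stimulus()] or 0/1 vector.
#' @return List with elements `flash_runs` and `silence_runs`.
#' @export
stimulus_runs <- function(stim) {
  stim <- as_binned_stimulus(stim)
  r <- rle(stim$x)
  list(flash_runs   = r$lengths[r$values == 1L],
       silence_runs = r$lengths[r$values == 0L])
}

#' Discretise a flash-onset schedule onto the bin grid
#'
#' Bin `t` (0-based internally; returned as position `t + 1`) is set to 1 iff
#' at least one flash onset falls in the half-open interval
#' `[t * bin_ms, (t + 1) * bin_ms)`.
#'
#' @param onsets_ms Strictly increasing flash onset times in ms, `>= 0`.
#' @param bin_ms Bin duration in ms.
#' @param n_bins Number of bins; defaults to the smallest grid covering all
#'   onsets.
#' @return A [binned_stimulus()].
#' @examples
#' binarize(c(0, 240), n_bins = 3)$x   # 1 0 1
#' @export
binarize <- function(onsets_ms, bin_ms = 120, n_bins = NULL) {
  if (length(onsets_ms) > 0) {
    if (any(onsets_ms < 0)) stop("flash onsets must be >= 0 ms", call. = FALSE)
    if (is.unsorted(onsets_ms, strictly = TRUE)) {
      stop("flash onsets must be strictly increasing", call. = FALSE)
    }
  }
  idx <- floor(onsets_ms / bin_ms)
  if (is.null(n_bins)) n_bins <- if (length(idx)) max(idx) + 1 else 0L
  n_bins <- as.integer(n_bins)
  if (length(idx) && any(idx >= n_bins)) {
    stop("`n_bins` too small to contain all onsets", call. = FALSE)
  }
  x <- integer(n_bins)
  x[unique(idx) + 1L] <- 1L
  binned_stimulus(x, bin_ms = bin_ms)
}

#' Flash onset times of a binned stimulus
#'
#' Places one flash onset at the start of every flash bin (the 40 ms flash +
#' 80 ms gap convention means within-run onsets are 120 ms apart).
#'
#' @param stim A [binned_stimulus()] or 0/1 vector.
#' @return Numeric vector of onset times in ms.
#' @export
flash_onsets <- function(stim) {
  stim <- as_binned_stimulus(stim)
  (which(stim$x == 1L) - 1) * stim$bin_ms
}

#' Enumerate all binary stimulus histories of a given length
#'
#' Returns the `2^n` binary sequences of length `n` in binary-counting order
#' with the oldest bin as the most significant digit, so row `k` encodes the
#' integer `k - 1`.  Column 1 is the oldest bin; column `n` the most recent.
#' This is the canonical node order used by the tree-plot analyses.
#'
#' @param n History length, between 1 and 20.
#' @return Integer matrix with `2^n` rows and `n` columns of 0/1.
#' @export
enumerate_histories <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n > 20) {
    stop("`n` must be a single integer in [1, 20]", call. = FALSE)
  }
  n <- as.integer(n)
  codes <- 0:(2^n - 1L)
  m <- vapply(seq_len(n),
              function(j) as.integer((codes %/% 2^(n - j)) %% 2),
              integer(length(codes)))
  matrix(as.integer(m), nrow = length(codes), ncol = n)
}

#' Generate the full stochastic flash-sequence stimulus
#'
#' Concatenates one block per value of `p_flash`, each block alternating
#' NB-distributed flash runs and geometric silence runs, mirroring the
#' three-condition experimental protocol (the conditions share mean run
#' lengths and are pooled for analysis).
#'
#' @param n_bins Total number of 120 ms bins (split evenly across blocks).
#' @param p_flash NB `p` parameter for each block.
#' @param mean_flash Mean flash-run length (bins).
#' @param mean_silence Mean silence-run length (bins).
#' @param bin_ms Bin duration in ms.
#' @param seed Optional integer seed.
#' @return A [binned_stimulus()] with a `blocks` attribute giving each
#'   block's `p` and bin range.
#' @export
generate_stimulus <- function(n_bins = 10000, p_flash = c(0.98, 0.8, 0.01),
                              mean_flash = 7, mean_silence = 9,
                              bin_ms = 120, seed = NULL) {
  stopifnot(n_bins >= 10, length(p_flash) >= 1)
  block_len <- diff(floor(seq(0, n_bins, length.out = length(p_flash) + 1)))
  .with_seed(seed, {
    xs <- vector("list", length(p_flash))
    blocks <- data.frame(p = p_flash, start = NA_integer_, end = NA_integer_)
    pos <- 0L
    for (b in seq_along(p_flash)) {
      per_block <- block_len[b]
      fp <- run_length_params("flash", p = p_flash[b], mean_run = mean_flash)
      sp <- run_length_params("silence", mean_run = mean_silence)
      chunk <- ceiling(1.5 * per_block / (mean_flash + mean_silence)) + 20L
      x <- integer(0)
      while (length(x) < per_block) {
        fr <- sample_runs(fp, chunk)
        sr <- sample_runs(sp, chunk)
        x <- c(x, build_stimulus(fr, sr)$x)
      }
      x <- x[seq_len(per_block)]
      xs[[b]] <- x
      blocks$start[b] <- pos + 1L
      blocks$end[b] <- pos + per_block
      pos <- pos + per_block
    }
    out <- binned_stimulus(unlist(xs), bin_ms = bin_ms)
    attr(out, "blocks") <- blocks
    out
  })
}
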