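#!/usr/bin/env Rscript
# Stage 1 — generate the stimulus and a synthetic population recording.
#
# Draws the three-condition stochastic flash sequence (NB flash runs of mean
# 7, geometric silences of mean 9, p in {0.98, 0.8, 0.01}), samples a
# 20-cell population of adaptive-surprise cells with bimodal prior
# strengths, and simulates 70 repeats of Poisson spiking.  Writes the
# stimulus, the ground truth and per-cell counts under results/data/.

library(rgcsurprise)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- population_spec()   # 20 cells, 1e4 bins (~20 min), 70 repeats
n_bins <- round(spec$stimulus_minutes * 60 * 1000 / spec$bin_ms)

stim <- generate_stimulus(n_bins = n_bins, seed = seed)
cells <- sample_population(spec, seed = seed + 1L)
truth <- attr(cells, "truth")
recs <- generate_recording(cells, stim, repeats = spec$repeats,
                           seed = seed + 2L)

write.csv(data.frame(bin_index = seq_along(stim$x) - 1L, x = stim$x),
          file.path(out, "stimulus.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, bin_ms = stim$bin_ms, n_bins = n_bins,
       blocks = attr(stim, "blocks"), mean_flash = 7, mean_silence = 9),
  file.path(out, "stimulus_meta.json"), auto_unbox = TRUE, digits = NA)
write.csv(truth, file.path(out, "truth.csv"), row.names = FALSE)
for (k in seq_along(recs)) {
  write.csv(recs[[k]],
            file.path(out, sprintf("counts_cell%02d.csv", k)),
            row.names = FALSE)
}

fr <- stimulus_runs(stim)
cat(sprintf("stimulus: %d bins, %d flash runs (mean %.2f), %d silence runs (mean %.2f)\n",
            length(stim), length(fr$flash_runs), mean(fr$flash_runs),
            length(fr$silence_runs), mean(fr$silence_runs)))
cat(sprintf("population: %d cells (%d weak / %d strong prior)\n",
            nrow(truth), sum(truth$label == "weak"),
            sum(truth$label == "strong")))
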