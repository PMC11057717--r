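#!/usr/bin/env Rscript
# Stage 3 — diagnostic analyses of the fitted models.
#
# Reuses the fits written by 02_fit.R (no refitting): rebuilds each cell's
# fitted model from fit_params.json, then computes tree-plots of data and
# adaptive-model predictions, OSR curves, per-depth data/model correlation,
# branching distance, the short-vs-long history correlation, and prior
# summaries with the strong/weak split.  Model comparisons (adaptive vs
# fixed, adaptive vs Markov-2, reduced vs fixed) use the paired Wilcoxon
# signed-rank test on the per-cell tree correlations from fits.csv.
# Tables land under results/diagnostics/.

library(rgcsurprise)

data_dir <- "results/data"
fit_dir <- "results/fits"
out <- "results/diagnostics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

stim <- binned_stimulus(read.csv(file.path(data_dir, "stimulus.csv"))$x)
truth <- read.csv(file.path(data_dir, "truth.csv"))
fits <- read.csv(file.path(fit_dir, "fits.csv"))
params <- jsonlite::read_json(file.path(fit_dir, "fit_params.json"),
                              simplifyVector = TRUE)
count_files <- sort(list.files(data_dir, "^counts_cell", full.names = TRUE))
depth <- 8L

as_cell <- function(p) {
  belief <- if (p$model %in% c("fixed", "markov2")) {
    markov_model(p$theta)
  } else {
    belief_prior(p$alpha0, p$beta0, p$eta)
  }
  cell_model(belief, p$a, p$b, reduced = identical(p$model, "adaptive_reduced"))
}

rows_osr <- list(); rows_depth <- list(); rows_branch <- list()
svl <- numeric(length(count_files))
ad_cells <- list()
for (k in seq_along(count_files)) {
  counts <- as.matrix(read.csv(count_files[k]))
  data_mean <- rowMeans(counts)
  tree_data <- history_conditioned_means(data_mean, stim, n = depth)
  ad_cells[[k]] <- as_cell(params[[sprintf("cell%02d_adaptive", k)]])
  tree_model <- history_conditioned_means(predict_rates(ad_cells[[k]], stim),
                                          stim, n = depth)

  oc_d <- osr_curve(tree_data, depth - 1L)
  oc_m <- osr_curve(tree_model, depth - 1L)
  rows_osr[[k]] <- data.frame(cell = k, k = oc_d$k, data = oc_d$mean,
                              model = oc_m$mean)
  rc <- tree_correlation_by_depth(tree_data, tree_model)
  rows_depth[[k]] <- data.frame(cell = k, depth = rc$depth, r = rc$r)
  bd <- branching_distance(tree_data)
  bm <- branching_distance(tree_model)
  rows_branch[[k]] <- data.frame(cell = k, depth = bd$depth,
                                 data = bd$distance, model = bm$distance)
  svl[k] <- short_vs_long_history_correlation(data_mean, stim,
                                              short_depth = 2,
                                              long_depth = 10)
  cat(sprintf("cell %02d analysed\n", k))
}

write.csv(do.call(rbind, rows_osr), file.path(out, "osr_curves.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, rows_depth),
          file.path(out, "tree_correlation_by_depth.csv"), row.names = FALSE)
write.csv(do.call(rbind, rows_branch),
          file.path(out, "branching_distance.csv"), row.names = FALSE)
first_tree <- history_conditioned_means(
  rowMeans(as.matrix(read.csv(count_files[1]))), stim, n = depth)
write.csv(as.data.frame(first_tree), file.path(out, "treeplot_cell01.csv"),
          row.names = FALSE)

ps <- prior_summary(ad_cells)
ps$true_label <- truth$label
ps$short_vs_long_r <- svl
write.csv(ps, file.path(out, "prior_summary.csv"), row.names = FALSE)

corr_of <- function(kind) fits$correlation[fits$kind == kind][order(fits$cell[fits$kind == kind])]
cmp <- list(
  adaptive_vs_fixed = compare_fits(corr_of("adaptive"), corr_of("fixed")),
  adaptive_vs_markov2 = compare_fits(corr_of("adaptive"), corr_of("markov2")),
  reduced_vs_fixed = compare_fits(corr_of("adaptive_reduced"), corr_of("fixed")))
jsonlite::write_json(
  lapply(cmp, function(cc) cc[c("statistic", "p_value", "n_cells",
                                "degenerate", "unreliable")]),
  file.path(out, "model_comparisons.json"), auto_unbox = TRUE, digits = NA)

cat("\nlabel agreement (fit vs truth):", mean(ps$label == ps$true_label), "\n")
for (nm in names(cmp)) {
  cat(sprintf("%s: signed-rank statistic %.1f, p = %.3g\n",
              nm, cmp[[nm]]$statistic, cmp[[nm]]$p_value))
}
cat("short-vs-long history r: weak prior median",
    median(svl[truth$label == "weak"]), "| strong prior median",
    median(svl[truth$label == "strong"]), "\n")
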