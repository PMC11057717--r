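# rgcsurprise

Simulation, model fitting and diagnostics for **surprise coding by retinal
ganglion cells (RGCs)** driven by stochastic full-field flash sequences.

## The problem

When a rhythmic flash train stops, many RGCs fire at the moment the next
flash was expected — the *omitted stimulus response* (OSR).  If these cells
encode **surprise**, their responses should vary in a graded way with how
unexpected each flash or silence is, given the preceding sequence.  This
package implements that analysis for stimuli discretised into 120 ms binary
bins (`x_t = 1` for a flash): flash runs follow a shifted negative binomial
with mean 7 (dispersion conditions `p ∈ {0.98, 0.8, 0.01}`), silences a
geometric with mean 9.

A cell's firing rate is modelled as a softplus function of surprise,

    s_t = −log p(x_t | x_<t, θ),        λ_t = log(1 + exp(a·s_t + b)),

with Poisson spike counts per bin.  The internal model p(x_t | ·, θ) is one
of:

* **fixed surprise** — first-order Markov chain, transition probabilities
  θ₀ = p(flash | silence), θ₁ = p(flash | flash) known a priori (at most 4
  distinct rates, OSR independent of run length);
* **Markov-2** — second-order contexts (at most 8 rates, no OSR growth
  beyond 2 flashes);
* **adaptive surprise** — transition probabilities inferred through a
  beta-Bernoulli conjugate update with a leak η = 0.2 that exponentially
  forgets old transition counts.  Each context carries a beta prior
  (α₀ⁱ, β₀ⁱ); the predictive is the leaky pseudo-count ratio
  (ñ_{i→1} + α₀ⁱ) / (ñ_{i→0} + ñ_{i→1} + α₀ⁱ + β₀ⁱ).  The prior strength
  α₀ + β₀ sets how much a cell trusts its expectations; in the strong-prior
  limit the model collapses onto the fixed model;
* **dynamic belief** — grid-based Bayesian filtering with per-step change
  probability, the normative reference the leaky model approximates.

Cells are fitted by 50-start maximum likelihood on the Poisson
log-likelihood `L = Σ_t n_t log f_t − f_t`; diagnostics include
history-conditioned **tree-plots**, **OSR curves**, per-depth model/data
correlation, **branching distance**, refractory QC, OSR detection, and
prior-strength clustering (strong vs weak at `log(α₁ + β₁) = 7`).  A seeded
synthetic-population harness (`recovery_experiment()`) validates the whole
chain by parameter recovery.

## Worked example

Simulate a weak-prior adaptive cell, fit it back, and read out its OSR
curve:

```r
library(rgcsurprise)

stim <- generate_stimulus(n_bins = 6000, seed = 1)
stim
#> <binned_stimulus: 6000 bins of 120 ms, 2651 flashes>

truth  <- cell_model(belief_prior(c(1, 2), c(4, 2), eta = 0.2), a = 2, b = -1)
counts <- sample_counts(predict_rates(truth, stim), seed = 2, repeats = 20)

fit <- fit_cell(stim, counts, "adaptive", n_starts = 15, seed = 3)
fit
#> <fit_result adaptive: loglik=-89313.49, corr=0.982, 15 starts>

rbind(alpha0 = fit$params$belief$alpha0, beta0 = fit$params$belief$beta0)
#>        [,1] [,2]
#> alpha0 0.96 2.03     # truth: 1, 2
#> beta0  3.61 2.07     # truth: 4, 2
c(a = fit$params$a, b = fit$params$b)
#>         a         b
#>  2.014914 -1.004039  # truth: 2, -1
```

The recovered prior pseudo-counts, gain and bias sit next to the generating
values, and `corr = 0.982` is the Pearson correlation between the model's
and the data's mean responses across all 256 depth-8 stimulus histories.
The same data fitted with the fixed surprise model reaches only 0.917 —
the fixed model cannot track responses that depend on more than the
previous bin.  The OSR curve (mean response at the first silence after `k`
consecutive flashes) grows with `k`, the graded-surprise signature:

```r
tree <- history_conditioned_means(rowMeans(counts), stim, n = 8)
osr_curve(tree, 6)
#>   k     mean n_obs
#> 1 1 1.613649   359
#> 2 2 1.788103   290
#> 3 3 1.812590   278
#> 4 4 1.829104   268
#> 5 5 1.867532   231
#> 6 6 1.919845   194
```

## Analysis workflow

The `analysis/` scripts run the full study on synthetic ground truth,
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # stimulus + 20-cell population + 70-repeat recording
Rscript analysis/02_fit.R         # 50-start ML fits of all four model kinds
Rscript analysis/03_diagnostics.R # tree-plots, OSR curves, comparisons, prior summaries
Rscript analysis/04_recovery.R    # the seeded end-to-end parameter-recovery report
```

At the default scale (20 cells, 10⁴ bins, 70 repeats) the recovery report
shows a median absolute error of 0.36 on the flash-context log prior
strength, perfect strong/weak label agreement, and the adaptive model
beating the fixed model on every weak-prior cell (two-sided Wilcoxon
signed-rank p = 1.5e-05).

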