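Package: rgcsurprise
Title: Surprise Coding Models for Retinal Ganglion Cell Responses to
    Stochastic Flash Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, fitting and diagnostic analysis of surprise
    encoding by retinal ganglion cells driven by stochastic full-field
    flash sequences. Provides generators for negative-binomial /
    geometric run-length stimuli on a 120 ms grid, a family of internal
    belief models (fixed first- and second-order Markov, leaky
    beta-Bernoulli adaptive inference, and a grid-based dynamic-belief
    reference filter), a surprise-to-rate Poisson spike encoder,
    multi-start maximum-likelihood fitting of cell parameters,
    history-conditioned tree-plot and omitted-stimulus-response
    analyses, and a seeded synthetic-population parameter-recovery
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
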