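Package: insideout
Title: Time-Reversal Irreversibility and Directed Hierarchy of Neural Amplitude Envelopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the arrow of time in multichannel amplitude-envelope
    recordings by comparing forward and time-reversed lagged cross-correlations
    (the INSIDEOUT framework), and derives directed-hierarchy summaries from the
    incoming-outgoing asymmetry of every region. Provides the full analysis
    pipeline around the core statistic: envelope construction (band-pass
    filtering, symmetric orthogonalization, Hilbert envelopes, epoching), lag
    selection by cross-validation with permutation inference, cluster-based
    permutation tests over lags, repeated-measures ANOVA contracts,
    recurrence-network dynamics of sliding-window hierarchy metrics with
    coherent phase-randomized surrogates, random-forest comparison of metric
    families, and variogram-matched spatial null models for brain-map
    correlations. Includes a synthetic-cohort generator with controllable
    directional coupling asymmetry so every stage is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nortest,
    emmeans,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
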