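Package: eipr
Title: Directed Coupling in Multichannel Biosignals via the
    Extrinsic-to-Intrinsic Power Ratio
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies directed synchronization in multichannel
    electrophysiological recordings (ECoG/EEG) by windowed vector
    autoregressive modelling. Each channel is regressed on its own past and
    on a data-driven extrinsic channel set selected by greedy forward search
    under the Bayesian information criterion. Directed coupling is
    quantified in the time domain by the extrinsic-to-intrinsic power ratio
    (EIPR), the variance of a source channel's partial contribution divided
    by the variance of the target's intrinsic contribution, with
    surrogate-data significance thresholds obtained by per-channel
    resampling. Partial directed coherence is provided as a frequency-domain
    comparator, together with spectral cross-checks, an analytic
    (Lyapunov-equation) oracle for linear benchmark systems, synthetic
    signal generators, a sliding-window analysis pipeline emitting directed
    coupling graphs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: TimeCourse, Network, Electrophysiology
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'simulate.R'
    'fit.R'
    'selection.R'
    'coupling.R'
    'significance.R'
    'pipeline.R'
    'graph.R'
    'io.R'
    'cli.R'
    'eipr-package.R'
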