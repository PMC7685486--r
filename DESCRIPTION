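Package: nesspipe
Title: Schema-Gated Analysis and Modeling Pipelines for Networked
    Social Science Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data model, pipeline execution engine, and analysis toolkit
    for networked behavioral experiments. Experiment event logs are
    transformed into a validated on-disk "data common specification"
    (experiment, phase, phase-description, player and action documents,
    each gated by a JSON Schema). A configuration-driven pipeline engine
    invokes analysis functions in order, validating every input and output
    at the function boundary and terminating gracefully on the first
    violation. Built-in functions cover temporal action analytics
    (progressions, histograms, request/reply deltas, discrete action
    sequences), property inference for Markov behavior models (transition
    matrices and their multinomial-logit parameterization), a discrete-time
    agent-based simulator of a collaborative anagram game, a synchronous
    graph dynamical system simulator with progressive threshold dynamics,
    and model-evaluation utilities (Kullback-Leibler comparison, R-squared,
    k-fold cross-validation). Synthetic-data generators emit complete
    multi-phase experiments for exercising every pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
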