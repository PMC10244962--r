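Package: imchain
Title: Absorbing Markov Chain Models of Intrusive Memory Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the temporal dynamics of intrusive trauma memories as a
    four-state absorbing discrete-time Markov chain (pre-trauma, consolidated
    intrusive memory, reactivated memory, non-intrusive memory). Builds
    transition matrices from interpretable intervention parameters (behavioural
    task strength, reminder-cue strength, lability probability, multi-cue
    models), quantifies persistence through fundamental-matrix absorption
    analysis, spectral decomposition and relaxation times, simulates
    time-inhomogeneous dosing schedules, runs Latin-hypercube sensitivity
    analyses of mixing times, and estimates transition probabilities from
    intrusion-diary count summaries under a Poisson model, with a synthetic
    diary generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
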