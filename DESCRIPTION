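Package: p53decode
Title: Decoding p53 Dynamics into Target mRNA and Protein Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the temporal pattern of a transcription
    factor (oscillatory versus rising p53) is decoded into the dynamics of its
    target mRNAs and proteins. Implements a discrete-time five-parameter
    production-degradation kinetic model with translational delay, fitting by
    maximising squared Pearson correlation, cross-condition prediction,
    fold-change/FDR/replicate-correlation differential-expression filters,
    fuzzy c-means clustering of z-scored time courses, a dynamical category
    table for paired mRNA/protein responses, simulators for decoding network
    motifs (activation thresholds, coherent and incoherent feed-forward
    loops), and between-condition area statistics. Ships a synthetic
    time-course generator emulating a two-condition, two-replicate hourly
    sampling design so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
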