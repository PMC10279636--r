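Package: alphanet
Title: Alpha-Band Phase-Locking Network Analysis of Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for parcel-level EEG functional connectivity in the
    alpha band and its graph-theoretic analysis. Provides a coupled-oscillator
    generator with von Mises phase coupling that emulates a two-condition by
    four-emotion within-subject design, deterministic preprocessing
    (resampling, average reference, zero-phase band-pass, epoching,
    moving-window artifact rejection, bad-channel detection), phase-locking
    value (PLV) connectivity matrices, proportional thresholding, modularity
    (weighted Louvain), global efficiency and core-to-extended routing
    efficiency of the face-processing network via Floyd-Warshall shortest
    paths, and linear mixed-effects inference with Satterthwaite F tests and
    Benjamini-Hochberg corrected pairwise contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph
Config/testthat/edition: 3
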