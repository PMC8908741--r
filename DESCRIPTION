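Package: grangerfold
Title: Granger Causality Analysis of Folding Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing causal structure in molecular dynamics
    trajectories of small folding proteins. Trajectories are featurized
    into inter-residue contact distances, modelled with multivariate
    autoregressive (MVAR) processes fitted by the Yule-Walker method, and
    summarized by a pairwise Granger causality matrix with per-contact
    predictability descriptors and a frame-shuffle significance test.
    Companion machinery builds TICA-based reaction coordinates, validates
    them with the transition-path probability criterion p(TP|xi), and
    characterizes the (un)folding pathway via free-energy profiles,
    committor functions, state discretization with medoid structures,
    and native-ensemble distance overlap. Synthetic-data generators with
    known causal ground truth support testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
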