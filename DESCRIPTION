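Package: coopmods
Title: Cooperative Functional Module Pair Discovery in Integrated
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects pairs of functional modules that cooperate in a
    cellular process by integrating protein-protein interaction data,
    directed transcription-factor regulatory links, and condition-specific
    expression profiles into a weighted physical interaction (WPI)
    network.  Module pairs are grown from high-scoring seed gene pairs by
    a greedy spanning algorithm driven by consistency, mediation and
    cooperation scores; genes correlated with both modules of a pair are
    identified against degree-preserving random-network null models and
    classified into five cooperation types; phase-specific cooperation is
    assessed with hypergeometric tests; and module-level cooperative
    networks and per-phase regulator-mediated relationship graphs are
    exported.  Includes a synthetic data generator with planted
    cooperative module pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
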