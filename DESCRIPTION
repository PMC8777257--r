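Package: csanet
Title: Hierarchical Neural-Network Connectivity Description and Generation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Headless toolchain for describing multiscale neural-network
    connectivity as a hierarchy of populations and super-populations,
    serializing models in an extended NetworkML (NeuroML 1.8.x lineage) XML
    dialect, expanding declarative connectivity patterns (all-to-all,
    one-to-one, pairwise Bernoulli, fixed fan-in, 2D Gaussian spatial,
    connectome-atlas based) into explicit connection lists via
    connection-set-algebra style masks, and splitting models into
    scale-specific sub-models with a co-simulation interface configuration.
    Includes programmatic builders for a cortical-microcircuit use case and
    a two-scale (spiking network plus neural-mass whole-brain) use case,
    plus a synthetic connectome-atlas generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
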