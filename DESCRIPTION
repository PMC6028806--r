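Package: expsim
Title: Map Structured Experiments onto Reaction-Network Models, Simulate, and Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for anchoring biochemical reaction-network models to
    structured experimental data. Experiment definitions (time-series,
    dose-response, multi-stimulus, and Hodgkin-Huxley current clamp) are read
    from a tab-separated five-block format, mapped onto a hierarchical model,
    the relevant sub-model is extracted and modified to match experimental
    conditions, the simulated experiment is run on a deterministic ODE engine,
    and the model is scored against the experimental readouts with a
    user-defined scoring expression. Per-experiment scores aggregate into a
    weighted battery score that feeds a local parameter-optimization loop.
    Models are read and written in a native hierarchical text dialect and in
    SBML Level 3 (with the groups package for pathway structure).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
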