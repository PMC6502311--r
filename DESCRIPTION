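Package: epidiverge
Title: Epistatic Networks and the Evolution of Hybrid Fitness During
    Allopatric Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of F1 hybrid fitness between two
    populations diverging in allopatry on a pairwise epistatic fitness
    network. Estimates independent and epistatic selection coefficients
    from double-knockout fitness tables (or generates synthetic networks
    with the same statistical structure), simulates sequential
    substitution under selection and drift using Kimura's diffusion
    fixation probability on background-dependent effective selection
    coefficients, and evaluates the closed-form trajectory of relative
    hybrid fitness, including transient heterosis and its replacement by
    postzygotic isolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
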