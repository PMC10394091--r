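Package: fractumor
Title: Fractional-Order Tumor-Immune-Metastasis Dynamics with Therapy Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a Caputo fractional-order
    compartmental model of lung tumor growth, immune response and metastatic
    spread, with combined immunotherapy and surgery. Provides a full-memory
    Adams-Bashforth-Moulton predictor-corrector solver for Caputo initial
    value problems with a Mittag-Leffler verification oracle, steady-state
    and local stability analysis (Jacobian, Routh-Hurwitz, numeric Lyapunov
    traces), reproduction number and coefficient at the disease-free
    equilibrium, normalized parameter sensitivities by finite differences,
    Pontryagin forward-backward sweep optimization of combined therapy, and
    closed-loop PID dosage scheduling. Includes reproducible named presets,
    configuration loading, trajectory serialisation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
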