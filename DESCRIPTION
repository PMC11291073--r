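Package: voltclamp
Title: Simulation and Correction of Whole-Cell Voltage-Clamp Experimental Artefacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of whole-cell patch-clamp voltage-clamp
    experiments, including series resistance, pipette and membrane capacitance,
    voltage offset, seal leak, and the amplifier compensation circuitry (series
    resistance compensation, supercharging/prediction, capacitance compensation,
    and leak subtraction). Ionic currents are pluggable; an electrical model
    cell and a generic Hodgkin-Huxley fast sodium current are provided. The
    package includes step-protocol builders, current-voltage curve extraction,
    virtual-population bias studies (I-V averaging bias and mutant/drug
    mischaracterisation), and multi-restart derivative-free fitting of the
    coupled cell-amplifier model to recorded current traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
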