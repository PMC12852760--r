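Package: raffsim
Title: Rotating-Frame Relaxometry with RAFFn Pulse Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rotating-frame relaxation MRI built around Relaxation
    Along a Fictitious Field (RAFFn) pulse trains. Constructs RAFFn and
    stretched RAFF2 rotary-echo pulse packets and comparison pulses (CW
    spin-lock, adiabatic half passage, hyperbolic-secant HS1/HS4, hard
    pulses), simulates two-pool Bloch-McConnell spin dynamics under arbitrary
    shaped-pulse trains with a dipolar relaxation model, fits the
    dual-polarity steady-state decay model jointly to +Z and -Z signal
    curves, produces pixel-wise relaxation and steady-state maps, generates
    synthetic short-axis cardiac phantoms with infarct/remote/healthy
    regions, and summarises infarct contrast as the relative relaxation time
    difference (RRTD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    deSolve,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
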