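Package: tdds
Title: Dynamic Performance of Diffusion-Controlled Transdermal Delivery
    Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models diffusion-controlled transdermal patches as two-layer
    Fickian transport (vehicle or membrane plus skin) with an interfacial
    partition coefficient, and quantifies how fast each device approaches
    its long-time behaviour. Provides steady-state flux for reservoir
    devices, Laplace-domain flux and cumulative-release transforms with
    numerical inversion (fixed-Talbot and Euler-summation backends),
    closed-form and moment-operator effective time constants (first-moment
    relaxation times) for reservoir and monolithic matrix systems,
    dimensional release profiles, parameter elasticities of the release
    time, and an independent Crank-Nicolson finite-difference solver of the
    governing equations against which all transform-based results can be
    verified.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
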