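Package: dnfip
Title: Dynamic Neural Fields with Intrinsically Plastic Gain and Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates one-dimensional dynamic neural fields (Amari-type
    lateral-interaction dynamics on a periodic feature dimension) whose
    global sigmoid gain and bias self-adapt online by intrinsic plasticity,
    in plain-gradient and natural-gradient (online Fisher estimate with
    Tikhonov regularization) variants, so that the field's scalar output
    measure matches an exponential target distribution. Includes a
    population-coded synthetic tactile input generator, sliding-window
    evaluation statistics (output histograms, input-output correlation),
    and reproducible experiment runners for input scale and offset
    manipulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
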