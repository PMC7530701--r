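Package: inrf
Title: Intrinsically Nonlinear Receptive Field Models for Vision Science
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling visual neurons with an intrinsically
    nonlinear receptive field (INRF): a summation operator in which a
    sigmoidal dendritic nonlinearity is shifted by a local mean of the
    stimulus, so that the same fixed unit can reproduce response reversals
    and brightness phenomena that force classical linear receptive fields
    to change with the input.  The package provides the operator itself
    (a literal reference evaluator, a fast level-decomposition evaluator,
    and point evaluation), the linear and linear-nonlinear comparison
    models, photoreceptor front-ends (Naka-Rushton, CIELAB lightness,
    power laws), seeded generators for classical psychophysics stimuli
    (ON/OFF bar signals, brightness-scaling displays, White's illusion
    gratings with bandpass noise, irradiation steps), the four experiment
    pipelines built on them, a full-reference image quality metric based
    on the model, a small trainable multi-channel INRF layer, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
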