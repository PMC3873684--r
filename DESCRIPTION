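Package: skinperm
Title: Membrane and Skin Concentration Prediction from Permeation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fickian diffusion modelling of drug permeation through artificial
    (silicone) membranes and skin. Provides closed-form series solutions of
    Fick's second law for a homogeneous membrane under constant-donor/sink
    conditions, steady-state algebra and a Crank-Nicolson solver for a
    two-layer stratum-corneum/viable-epidermis skin model, nonlinear
    least-squares estimation of partition (K) and diffusion (D) parameters
    from cumulative-permeation time courses, steady-state membrane and skin
    concentration prediction, cross-membrane (silicone to skin) linear
    calibration, and a virtual Franz diffusion-cell experiment generator
    with sampling-and-replacement data reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
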