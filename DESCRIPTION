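Package: neuromat
Title: Functional Maturation Readouts for iPSC-Derived Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for patch-clamp and calcium-imaging readouts of
    neuronal functional maturation. Implements five-category classification of
    induced action-potential activity, spike morphometry with a third-derivative
    threshold criterion, voltage-clamp peak-current extraction with Boltzmann
    activation/inactivation fitting and availability-window analytics, and
    delta-F/F power-spectral analysis of spontaneous calcium oscillations.
    Includes a synthetic-recording generator with known ground truth for
    validating every analysis stage, plus cohort tally, group-comparison and
    2^-ddCt reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
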