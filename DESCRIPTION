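Package: figana
Title: Automatic Generation and Rasch/LLTM Calibration of Figural Analogy Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based automatic generation of figural analogy test items
    (A:B::C:D) built from a canonical geometric figure: rotation, reflection,
    trapezium rotation, line subtraction and dot movement rules, isomorph
    enumeration over the incidental space, Solutions-Combination-Design
    distractor assembly, and rendering of complete items with answer keys.
    Includes the psychometric machinery used to evaluate such items:
    conditional maximum likelihood estimation of the Rasch model and the
    Linear Logistic Test Model (LLTM), Andersen likelihood-ratio, Wald and
    deviance model tests, Cronbach's alpha, and a seeded response simulator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
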