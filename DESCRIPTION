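Package: chrysodev
Title: Thermal Development Models and Postmortem Interval Estimation for
    Chrysomya megacephala
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Developmental reference data and models for the oriental latrine
    fly Chrysomya megacephala (Diptera: Calliphoridae), reared at seven
    constant temperatures (16-34 degrees C). Implements the Ikemoto-Takai
    linearized thermal summation model (developmental threshold temperature
    D0 and thermal summation constant K per stage), cubic larval growth
    curves in both directions (length from age, age from length), isomorphen
    and isomegalen diagram construction, intra-puparial sub-stage age
    bracketing, degree-hour accumulation over arbitrary temperature records,
    and composition of these pieces into minimum postmortem interval
    (PMI_min) estimates from case evidence. A stochastic cohort simulator
    generates synthetic rearing experiments and case scenarios with the
    statistical structure the models assume, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
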