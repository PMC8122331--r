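Package: metadose
Title: Radionuclide Dosimetry for Simulated Metastatic Dissemination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of metastatic dissemination from a
    Gompertzian primary tumor, sphere absorbed-fraction dosimetry for
    therapeutic radionuclides (90Y, 131I, 177Lu, 161Tb, 225Ac) under a
    straight-track continuous-slowing-down transport model, and a
    linear-quadratic tumor-control chain that solves the activity
    concentration and required absorbed dose achieving a target
    metastatic control probability across simulated patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
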