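Package: accuprofile
Title: Accuracy-Profile Validation Statistics for Targeted LC-MS/MS Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for the validation of targeted quantitative
    LC-MS/MS assays under the total-error (accuracy profile) framework, as
    used in therapeutic drug monitoring. Implements calibration modelling
    (linear and quadratic fits, optionally on the log-log scale, with
    inverse prediction), one-way random-effects variance components for
    repeatability and intermediate precision, beta-expectation tolerance
    intervals with Satterthwaite degrees of freedom, accuracy profiles with
    LLOQ/ULOQ determination, expanded measurement uncertainty, and the full
    suite of bioanalytical acceptance checks (selectivity, crosstalk,
    carryover, matrix effect, stability, freeze-thaw, dilution integrity,
    inter-laboratory comparison, signal-to-noise based limit of detection).
    A synthetic-data generator emulating a multi-day validation design with
    known ground truth makes every stage testable end-to-end. Ships the
    concentration design and validation summary of a seven-analyte CFTR
    modulator (caftor) panel as the default worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
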