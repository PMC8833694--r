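Package: lnscore
Title: Lymph-Node Involvement Scoring from Preclinical 3D and Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of lymph-node metastatic involvement from
    preclinical ultrasound in a paired left/right (tumor-draining vs control)
    design. Computes node morphometry (Cavalieri volume from serial B-mode
    contour stacks, longest diameter and perpendicular width, roundness) and
    bolus-kinetic perfusion parameters (arrival time, time-to-peak, wash-in
    rate) from contrast-enhanced ultrasound time-intensity curves with
    motion-excluded frames; applies a five-parameter binary scoring system
    with a sum score robust to missing perfusion data; and evaluates the
    scores against histopathology with exact (Clopper-Pearson) confidence
    intervals on sensitivity, specificity, predictive values and accuracy.
    Includes a synthetic-cohort generator reproducing the statistical
    structure of a paired small-animal study, and an embedded reference
    score matrix for end-to-end reproduction of the published diagnostic
    performance table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
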