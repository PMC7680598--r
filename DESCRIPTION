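Package: patellaxis
Title: Axis-Based Measurement of Patellar Height and Joint-Line Position
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Landmark-based morphometry of lateral knee radiographs for total
    knee arthroplasty (TKA) assessment. Implements the tibial-shaft-axis
    measurement method for patellar height and joint-line position - the
    axis-patella (AP) index, joint axis-patella (jAP) index and joint line
    height (JLH) - alongside the four classical patellar-height indices
    (Insall-Salvati, modified Insall-Salvati, Caton-Deschamps,
    Blackburne-Peel) and the posterior tibial slope. Includes a rule-based
    discriminator for true versus pseudo patella baja from paired
    pre/post-operative measurements, reliability and validity statistics
    (intraclass correlation coefficients with exact F confidence intervals,
    Pearson correlation, paired t tests, Bland-Altman limits of agreement),
    a parametric synthetic-knee landmark simulator with an observer noise
    model for validation at known ground truth, and command-line entry
    points for measurement, comparison, reliability and simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
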