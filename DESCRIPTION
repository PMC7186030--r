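Package: eitperf
Title: Functional Electrical Impedance Tomography of Regional Lung Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for imaging regional lung
    perfusion by electrical impedance tomography (EIT) with a conductive
    saline bolus. Provides a two-dimensional thoracic phantom with tidal
    ventilation and regional indicator-dilution kinetics under distal and
    proximal (occluded or open) pulmonary-artery injection scenarios, a
    finite-volume forward solver for the 16-electrode adjacent-drive
    protocol, normalized-difference back-projection and regularized
    sensitivity reconstruction of 32x32 relative impedance images,
    functional images of regional ventilation and perfusion, local
    time-impedance dilution curves with Stewart-Hamilton metrics (area
    under the curve, appearance time, appearance-to-peak time, mean
    transit time), relative regional flow estimation, and
    perfusion-defect detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
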