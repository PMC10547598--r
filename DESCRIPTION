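Package: rootsense
Title: Image-Based Prediction of Boiled Sweetpotato Flesh Colour and Mealiness
Version: 0.1.0
Authors@R: person("Root", "Phenotyping Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to predict two sensory attributes of boiled sweetpotato
    roots, flesh-colour intensity and mealiness by hand (both on a 0-10
    panel scale), from RGB photographs of root cross-sections. The pipeline
    covers training-free root detection, K-means background elimination,
    colour (RGB/HSV/CIELAB) and texture (edge/contour graininess) feature
    extraction, regression and classification model training with
    cross-validation and error analysis, detector evaluation (IoU, mAP),
    a synthetic-image generator with exact ground truth for offline
    verification, and a command-line interface for batch prediction with
    CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    jsonlite,
    yaml,
    quadprog,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
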