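Package: adlsense
Title: Multi-Label Detection of Activities of Daily Living from Smartphone and Ambient Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid pipeline for detecting Activities of Daily Living (ADLs)
    from smartphone and smart-home ambient sensor streams. Includes
    threshold-based phone-on-table detection, a convolutional network that
    classifies low-level activities (lying down, on table, sitting, standing,
    walking) from 6-second accelerometer windows, bespoke feature construction
    from phone usage, step, light, room-location, fridge, appliance-power and
    room-light streams, cleaning rules for self-reported multi-label activity
    intervals, a densely-labeled multi-label LSTM sequence model trained with a
    masked balanced binary cross-entropy loss, multi-label evaluation machinery
    including a prediction-label flattening algorithm and a joint confusion
    matrix with false-positive/false-negative margins, and a seedable synthetic
    session generator so the whole pipeline is testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
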