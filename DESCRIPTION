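Package: swtams
Title: Smartwatch-Based VO2max Estimation and Acute Mountain Sickness Risk Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates maximum oxygen consumption (VO2max) from submaximal
    outdoor-run heart-rate and speed traces recorded by a wrist device:
    moving-average filtering, activity detection, artifact exclusion
    (downhill pattern, heart-rate rise at zero speed, short high-intensity
    bursts), heart-rate-zone segmentation, and weighted linear extrapolation
    of the theoretical oxygen cost of running (3.5 x speed in km/h) to
    maximum heart rate. Includes method-agreement statistics against a
    reference measurement (constant error, paired t, Pearson, two-way
    intraclass correlation, MAE/MAPE, Bland-Altman limits of agreement), an
    acute mountain sickness (AMS) risk layer (Woolf odds ratios, logistic
    models, ROC curves, Youden-optimal operating points, paired DeLong AUC
    comparison), and a synthetic-data generator producing run sessions with
    known true VO2max and cohorts with a prescribed error and odds-ratio
    structure, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
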