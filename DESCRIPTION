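Package: fogbench
Title: Evaluation Methodology for Wearable-Sensor Freezing-of-Gait Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking per-sample freezing-of-gait (FOG) detectors
    built on a single lower-back accelerometer. Implements the competition-style
    scoring metric (per-class average precision over masked per-sample
    confidences, averaged across the three FOG classes), precision-recall and
    ROC operating-point analysis, episode extraction with the three
    gold-standard outcomes (percent time frozen, episode count, total
    duration), rater-agreement statistics (two-way absolute-agreement
    intraclass correlations with F-based confidence intervals, Cohen's d), the
    Benjamini-Krieger-Yekutieli two-stage false-discovery-rate procedure, and a
    daily-living pipeline producing bout-restricted hourly and daily percent
    time frozen with the associated non-parametric group comparisons. A
    synthetic accelerometer and detector generator emulates the protocol and
    week-long 24/7 recording formats so every stage is exercisable without
    access to the original competition data or trained models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
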