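Package: tdscreen
Title: Transcriptional Disease Signature Screening of Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening compounds against a transcriptional disease
    signature (TDS) measured on probe-count platforms such as NanoString
    nCounter. Provides positive-control, housekeeper and background
    normalization of probe counts; construction of a weighted disease gene
    signature from case/control cohorts via fold change, Welch tests,
    false-discovery-rate control and ROC-AUC marker weighting; compound
    scoring with a signed activation Z-score and a Kolmogorov-Smirnov drug
    score; calibration of significance thresholds by all-pairs comparison and
    randomized-null resampling; and a synthetic cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
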