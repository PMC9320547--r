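Package: anoikisflux
Title: Bioenergetic Stress-Test Metrics and Consistent-Direction
    Expression Screening for Detachment-Stressed Cancer Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the bioenergetic switch of tumour cells
    under detachment (anoikis) stress. Derives glycolysis and
    mitochondrial stress-test metrics (basal glycolysis, glycolytic
    capacity and reserve, ATP-linked respiration, proton leak, spare
    respiratory capacity, OCR/ECAR ratio) from injection-scheduled
    extracellular-flux traces; mines gene-set collections (GMT) by
    keyword and screens expression studies for genes with a consistent
    direction of change across cell lines; quantifies supporting assays
    (2^-ddCt qPCR, proliferation ratios, relative lactate, ROS relative
    percentage, dose-response sensitivity scores); and ships seeded
    synthetic-data generators that emulate each input so every estimator
    can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
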