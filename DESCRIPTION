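Package: renaltox
Title: Long-Term Kidney Toxicity Analysis for 177Lu-Octreotate Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for late radiation-induced kidney toxicity
    in mice after 177Lu-octreotate administration. Implements MIRD
    pamphlet-21 self-dose kidney dosimetry from time-activity curves,
    differential expression of kidney cortex and medulla transcripts against
    age-matched controls (quantile normalization, variance filtering, Welch
    tests, Benjamini-Hochberg adjustment with a dual significance threshold),
    biomarker recurrence and dose-response analysis across dose-by-time
    groups, planar gamma-camera renal-function quantification
    (fractional-max ROI segmentation, syringe calibration, 99mTc-DTPA
    renograms and 99mTc-DMSA uptake), and blood-marker summary ratios.
    Ships a synthetic-data generator for every input (expression studies,
    biodistribution curves, Poisson-noise scintigraphy frames, blood panels)
    plus fixtures transcribed from the published marker, regulator, and
    blood-ratio tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    limma,
    stats,
    tiff,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
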