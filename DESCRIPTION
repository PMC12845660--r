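Package: fluorscreen
Title: Suspect Screening, Semi-Quantification and Risk Prioritization of
    PFAS in Surface Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated workflow for per- and polyfluoroalkyl substances
    (PFAS) in surface waters measured by liquid chromatography high-resolution
    mass spectrometry. Implements exact-mass and Kendrick mass-defect
    analytics with CF2/CH2 homologous-series detection, suspect-list matching
    with isotope-pattern and diagnostic-fragment evidence graded into
    identification confidence levels, surrogate response-factor
    semi-quantification with quality-control gating and method quantification
    limits, PFOA-equivalent environmental quality standard (EQS) compliance
    screening, a ToxPi-based hazard/exposure risk index for compound
    prioritization, and paired upstream/downstream nonparametric testing with
    false discovery rate control. A synthetic-data generator emulating a
    24-sample paired river survey with known ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
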