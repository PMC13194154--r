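Package: TILscore
Title: Spatial Quantification of Tumor-Infiltrating Lymphocytes and
    Rule-Based Immune Subtyping of Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the spatial distribution of tumor-infiltrating
    lymphocytes (TILs) on annotated whole-slide images of lung
    adenocarcinoma using a 100-micron patch grid, computes per-patch
    normalized lymphocyte densities and a per-slide high-aggregation
    TILs patch ratio score, and classifies slides into high- and
    low-immunity subtypes with an interpretable threshold rule.
    Includes a QuPath-compatible GeoJSON annotation reader/writer, a
    classical (non-learned) tissue-mask segmentation stage, interpolated
    TIL density heatmaps, diagnostic-accuracy statistics with Wilson
    confidence intervals and Mann-Whitney AUC, an immunohistochemistry
    composite Z-score reference standard, and a spatial point-process
    simulator (Poisson background plus Thomas-type clusters) that
    generates fully annotated synthetic cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
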