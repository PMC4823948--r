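Package: icdQuant
Title: Quantification of Immunogenic Cell Death Biosensor Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-analysis and statistics pipeline for high-content
    quantification of the hallmarks of immunogenic cell death: cytoplasmic
    calreticulin-GFP aggregation and quinacrine-stained ATP vesicles scored
    by a per-cell granularity statistic, nuclear HMGB1-GFP exodus, MX1-GFP
    type-1 interferon reporter induction, propidium-iodide viability gating
    of cytometry event tables, and tissue-level readouts (hematoxylin/eosin
    colour deconvolution, eosin-over-hematoxylin ratio, low-hematoxylin
    necrotic area fraction, leukocyte counts, percent marker-positive
    cells). Decision thresholds are calibrated from the Gaussian
    distributions of positive and negative control wells, wells are
    summarized as fractions of responding viable cells, and groups are
    compared with Welch-corrected t-tests. A seeded synthetic-data
    generator produces microscopy fields, event tables and stained tissue
    images with known ground truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    mclust,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: CellBiology, ImageAnalysis, FlowCytometry, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
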