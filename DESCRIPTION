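Package: medvis
Title: Quantitative Quality Scoring of Multi-Panel Scientific Figures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores raster figures of scientific papers on four image and
    caption derived metrics (white-space fraction, RGB colorfulness, edge
    complexity, and number of subpanel visualizations), embeds the metric
    vectors with PCA, t-SNE and UMAP, classifies each figure good or not-good
    by additive consensus over three two-group k-means clusterings, derives
    quartile thresholds with per-figure advice and gauge charts, and provides
    weight-sensitivity, validation and synthetic-corpus utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    jpeg,
    tiff,
    Rtsne,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
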