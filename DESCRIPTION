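Package: dpcseg
Title: Microfeature Segmentation of Biological Images by Improved
    Density-Peak Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments multi-feature biological images by combining
    SLIC-style superpixel preprocessing in a scaled (x, y, L, a, b)
    feature space with a density-peak-clustering core that selects
    cluster centers by an entropy-weighted decision score, propagates
    labels along nearest higher-density neighbours, and refines the
    pixel-level result with a variance-weighted spatial noise-isolation
    pass. Includes evaluation metrics (segmentation integrity rate,
    block-variance noise estimation, missing-feature count, adjusted
    Rand index, per-feature IoU), a seeded phantom-image generator with
    ground-truth masks, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    tools,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
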