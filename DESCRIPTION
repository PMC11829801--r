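Package: spotglyphs
Title: Scatter Bar and Scatter Pie Glyph Maps for Spatial Compositional Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Visualizes proportional data across spatially resolved
    coordinates, such as deconvolved cell-type proportions from spatial
    transcriptomics, by replacing each spot of a scatterplot with a stacked
    bar glyph (proportions encoded as segment lengths against a shared
    baseline) or a pie glyph (proportions encoded as wedge angles). Provides
    a pure geometry engine that turns a proportion matrix plus planar spot
    centroids into exact glyph coordinates, with automatic per-axis scale
    estimation, padding, overlap diagnostics, and JSON geometry export; a
    ggplot2-based renderer with a deterministic rainbow palette and a
    side-by-side pie-versus-bar comparison figure; a seeded generator of
    synthetic spatial compositional fields for testing; and a command-line
    interface. The aligned dataset is a SummarizedExperiment-derived S4
    class with category proportions as the assay and spot coordinates as
    column metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    patchwork,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
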