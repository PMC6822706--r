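Package: fungalfeatures
Title: Quantitative Characterization of Fungal Growth and Morphology from Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable image-analysis toolkit for quantifying phenotypes of
    filamentous fungi in 2-D micrographs: spore/conidia counting and per-spore
    morphometry (area, length, width, circularity from the best-fit ellipse),
    mycelium characterization through a skeleton-derived mathematical graph
    (total hyphal length, hyphal tip counts, convex-hull colony area, time
    series), and counting of nematode-trap structures. Includes pixelwise
    segmentation-accuracy metrics (precision, recall, F-measure, Matthews
    correlation coefficient) against ground-truth masks, a batch runner with
    calibration sweeps and overlay rendering, and a synthetic-scene generator
    that plants objects with exact ground truth so the full pipeline is
    testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
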