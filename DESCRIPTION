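Package: seedshape
Title: Seed Shape Quantification from Images and Geometric Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures classical seed shape descriptors (eccentricity index,
    aspect ratio, flatness index, circularity, roundness, rugosity) from
    seed images or caliper measurements, and quantifies the similarity of
    seed silhouettes to geometric model curves (cardioid, golden-ratio
    elongated cardioids, ellipse, ovoid) with the J index, a
    percentage-scaled intersection-over-union statistic. Includes silhouette
    extraction from raster images (automatic thresholding, connected
    components, sub-pixel contour tracing), regional and quadrant J values,
    morphotype classification, a ground-truthed synthetic seed image
    generator, and a command-line interface for batch measurement runs.
License: MIT
Encoding: UTF-8
Imports:
    polyclip,
    EBImage,
    png,
    tiff,
    grDevices,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
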