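Package: leafquant
Title: Quantification of Leaf Disease Symptoms from RGB Images
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipelines that quantify five visual disease
    symptoms on plant leaves photographed against a uniform bright panel:
    chlorosis level and localization from the yellow colour component,
    necrotic-area percentage from green/blue channel segmentation with a
    morphological opening prefilter, a deformation (sphericity) index from
    the leaf silhouette, white-spot area percentage via connected-component
    pixel accounting, and mosaic (vein-clearing) density on back-lit images
    via top-hat/bottom-hat contrast enhancement and Canny edge detection.
    Includes the underlying binary and grayscale mathematical-morphology
    operators, connected-component labelling, a Canny edge detector, and a
    parametric synthetic diseased-leaf generator with pixel-exact ground
    truth for validating every pipeline without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    jpeg,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
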