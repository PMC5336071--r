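Package: veinviz
Title: Near-Infrared Vein Visualization Image Pipeline and Module Design Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhancement and segmentation pipeline for near-infrared (NIR)
    trans-illumination images of subcutaneous veins: complex histogram
    equalization (the pixelwise average of global and contrast-limited
    adaptive histogram equalization), a multiscale 2D Hessian-based
    vesselness (Frangi) filter for dark curvilinear structures, adaptive
    mean thresholding, morphological closing, Zhang-Suen skeletonization
    and skeleton overlay. Also provides the trigonometric design
    calculator for a two-sided angled NIR illumination module (penetration
    angle and light width from vein depth and penetration depth) and a
    synthetic tissue-phantom image and attenuation simulator with known
    vein ground truth, so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tools,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
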