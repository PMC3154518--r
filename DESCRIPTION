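Package: vertascan
Title: Vertebra Detection and Segmentation in Spine Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automatic detection and segmentation of cervical vertebral
    bodies (C3-C7) in low-contrast spine radiographs. Provides contrast-limited
    adaptive histogram equalization with bilinear blending of regional
    transforms, a Canny edge detector (Gaussian smoothing, Sobel gradients,
    non-maxima suppression, hysteresis), corner detection by Douglas-Peucker
    polygonal approximation of traced edge contours, vertebra localization from
    a statistical spine-curvature model anchored on two user-supplied points,
    per-vertebra Active Shape Model segmentation with grey-level profile
    matching under the Mahalanobis distance, point-to-line segmentation error
    metrics with a 3-standard-deviation success/failure decomposition, and a
    seeded synthetic radiograph generator with exact ground truth for testing
    every stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
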