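Package: canopy3d
Title: 3D Crop Water Stress Mapping from Thermal and Binocular RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses low-resolution thermal imagery with a binocular RGB stereo
    pair into a 3D plant-canopy point cloud carrying per-point temperature,
    and extracts the three-dimensional distribution of the crop water stress
    index (CWSI). Implements coarse photogrammetric registration of the
    thermal image to the colour image (HSV canopy masking, feature matching,
    epipolar filtering, triangulation and back-projection, RANSAC
    homography), SSIM-maximising fine registration, semi-global block
    matching stereo with median filtering and multi-level mean hole filling,
    point-cloud cleaning (HSV filter, statistical outlier removal, k-means
    temperature clustering), CWSI computation against wet/dry reference
    temperatures, and a fully ground-truthed synthetic greenhouse scene
    generator for validation.
License: MIT
Encoding: UTF-8
Imports:
    png,
    yaml,
    jsonlite,
    grDevices,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
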