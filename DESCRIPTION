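Package: vbbank
Title: Virtual Bone Bank Matching of Structural Allografts from 3D Bone Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting the best-matching structural bone allograft
    from a virtual bone bank of CT-derived 3D models. Covers threshold
    segmentation of intensity volumes and isosurface reconstruction of bone
    surfaces, sagittal mirror-model creation from the healthy contralateral
    side, six-landmark ABC size measurements (transepicondylar width and
    medial/lateral anterior-posterior condylar depths), closest-ABC screening
    of a donor bank, landmark-initialized trimmed iterative-closest-point
    rigid registration, and a mean surface-distance goodness-of-match score
    with colorimetric distance mapping. Includes a parametric synthetic
    distal-femur generator with ground-truth landmarks, tumor-like surface
    defects, and CT-like rasterization for end-to-end validation without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
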