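Package: MammoAsym
Title: Bilateral Mammographic Asymmetry Detection by Radial Shape
    Signatures and Seeded Region Growing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computer-aided detection of bilateral asymmetry in screening
    mammograms. The left and right breast of a patient are compared along
    two complementary axes: morphological shape asymmetry, quantified by a
    centroid-to-perimeter radial signature aligned with dynamic time
    warping (DTW), and skin-thickness asymmetry, quantified from a skin
    rim segmented by seeded region growing. Includes DICOM ingestion with
    VOI LUT windowing, annotation removal by thresholding plus largest
    connected component, the ASSD and RVD segmentation-validation metrics
    with a parametric sweep harness, and a synthetic phantom generator
    that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    png,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
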