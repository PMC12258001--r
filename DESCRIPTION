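Package: csgarc
Title: Cut-Sort-Group Post-Processing for Dynamically Collimated Proton Arc Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for improving the delivery efficiency of dynamically
    collimated step-and-shoot proton arc therapy plans. Implements the
    Cut-Sort-Group (CSG) post-processing pipeline: removal of low-weight
    control points, sliding-window energy layer sorting (SWELS) to favour
    fast high-to-low energy transitions, and ant-colony grouping of spots
    into shared trimmer configurations. Includes a component-wise beam
    delivery time model (gantry kinematics, spot delivery, energy switching,
    trimmer travel), an analytic collimated pencil-beam dose engine with
    DVH-based plan quality indices (homogeneity, Paddick conformity,
    gradient index), a delivery-uncertainty robustness analysis, and a
    synthetic phantom/plan generator for end-to-end exercising without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
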