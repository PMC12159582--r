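Package: acetrecon
Title: Automated Reconstruction and Regional Analysis of Acetabular Bone Defects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs three-dimensional acetabular bone-defect geometry from
    a watertight surface mesh of a pathological hemipelvis. A PCA statistical
    shape model built from defect-free training anatomy estimates the native
    pelvis; spherical ray casting from the hip joint centre extracts the missing
    bone volume; the defect solid is clustered, surfaced and refined by mesh
    Boolean operations; and regional absolute defect volume, relative defect
    volume and defect depth are reported for the superior, anterior, posterior
    and medial-wall regions. Includes a parametric hemipelvis phantom generator
    with voxel-oracle ground truth for end-to-end validation (volumetric dice,
    volume errors, Hausdorff distance), plus low-level watertight-mesh
    utilities (STL input/output, ray casting, voxelization, Boolean volumes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
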