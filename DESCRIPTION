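Package: fundus3d
Title: Single-Image 3D Retinal Vessel Modelling and Hemodynamic Feature
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline turning a single colour fundus photograph
    into a three-dimensional vascular surface model and hemodynamic
    disease-classification features. Stages: weighted red/green channel
    fusion with a one-dimensional local search, vessel segmentation
    (a small DenseBlock-Unet trained from scratch, plus a Hessian
    vesselness fallback), Zhang-Suen skeletonization with
    endpoint/bifurcation detection and segment tracing, Canny-based
    vessel radius profiling along centerline normals, lofted circular
    cross-section surface meshing with junction repair and local
    Laplacian smoothing, triangle mesh quality reporting, a
    reduced-order pulsatile Poiseuille network flow solver with a
    per-face feature schema, and filter/wrapper feature selection with a
    leave-one-out classifier battery. Includes seeded synthetic fundus
    and vascular-tree generators with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    png,
    tiff,
    yaml,
    e1071,
    rpart,
    randomForest,
    xgboost,
    class
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
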