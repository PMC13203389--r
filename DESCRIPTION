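Package: meshdose
Title: Mesh-Based Radiotherapy Dose Estimation and Treatment Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for image-derived radiotherapy treatment simulation built
    on triangular organ meshes. Converts labeled organ point clouds into
    watertight surface models (nearest-neighbour label propagation,
    statistical outlier removal, voxelisation, isosurface extraction,
    Laplacian smoothing), traces radiation beams through the resulting
    meshes by ray casting, and estimates tumour dose with a buildup-tail
    percentage depth dose model including Mayneord source-to-surface
    corrections and equivalent-depth heterogeneity scaling. Also provides
    Lyman-Kutcher-Burman effective volume and normal tissue complication
    probability scoring, gantry-angle sweeps for beam selection, and
    conservative axis-aligned bounding box collision detection for the
    treatment machine. Synthetic nested-ellipsoid phantoms make every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    yaml,
    RNifti,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
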