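Package: zernike3d
Title: Rotation-Invariant 3D Zernike Descriptors for Macromolecular Structure Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts macromolecular structures (PDB format) into
    rotation-invariant three-dimensional Zernike descriptors computed from
    feature points extracted from four structural representations: the raw
    atomic point cloud, a Gaussian mixture model of the atoms, a decimated
    Gaussian-density isosurface mesh, and the full isosurface. Feature
    points are embedded in the unit ball, discretized on a cubic occupancy
    grid, converted to geometric moments and then to Zernike moments, whose
    per-(n,l) norms form the descriptor. Includes descriptor database
    construction over folders of PDB files, nearest-neighbour retrieval by
    Euclidean distance with statistical-significance annotation, top-k
    retrieval accuracy and ROC/PR evaluation, and deterministic synthetic
    fixtures (parametric point clouds and toy PDB files) so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite
Config/testthat/edition: 3
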