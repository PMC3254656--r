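Package: embryoshape
Title: Surface-Energy Modelling of Two-Cell Embryo Shape and Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanical modelling of the two-cell stage embryo as two
    bodies bounded by three tensioned surfaces (the two outer cortices and
    their contact surface) confined to an ellipsoidal eggshell. Provides a
    triangulated-mesh surface-energy minimizer with volume constraints and
    a one-sided shell constraint, Laplace-pressure extraction from the
    volume-constraint multipliers, a grid search over relative cortical
    tensions scored by iterative-closest-point registration against
    observed membrane contours, and the image-quantification stages that
    feed the fit: marker-based 3D watershed segmentation, voxel-count cell
    volumes, eggshell ellipsoid fitting, contact curve-depth measurement,
    kymograph velocimetry and cortical intensity normalization. A
    synthetic-data module generates embryo-like geometries, confocal-like
    two-channel stacks, kymographs and intensity traces so the whole
    pipeline can be exercised end to end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'geometry.R'
    'simulator.R'
    'fitting.R'
    'imaging.R'
    'synthetic.R'
    'pipeline.R'
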