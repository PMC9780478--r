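Package: hexcart
Title: Automated Hexahedral Cartilage Meshing from Segmented Knee Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline that turns segmented knee tissue label
    volumes into simulation-ready finite element meshes: triangular rigid-body
    bone surfaces remeshed by Voronoi clustering, and high-quality blended
    hexahedral cartilage meshes built by swept-extrusion raytracing with
    degenerate-element repair, scaled-Jacobian quality optimization, and
    cartilage-to-bone interface blending. Includes a template-registration
    attachment-site locator, mesh comparison metrics (surface deviation with
    nodal coverage, Dice similarity, min-max normalized RMS), synthetic joint
    phantoms with analytic ground truth for testing, plain-text mesh and
    Abaqus-INP export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    Matrix,
    signal,
    jsonlite,
    yaml,
    xml2,
    RNifti,
    stats,
    utils,
    tools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
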