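Package: cytoremodel
Title: Stretch-Induced Cytoskeletal Remodeling in 3D Tissue Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how contractile fibroblasts embedded in
    three-dimensional engineered tissue constructs remodel their actin
    cytoskeleton after a rapid, sustained uniaxial stretch.  Provides a
    sector-based mechanical simulator of stress-fiber depolymerization and
    stress-driven polymerization, a band-pass spectral "fibrosity" statistic
    for quantifying fibrous texture in fluorescence images, strain-field
    kinematics and affine estimation from bead displacements, temporal
    response classification with contingency-table statistics, and synthetic
    generators for every input the pipeline consumes (fibrous-cell image
    series, bead fields, and isometric force traces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
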