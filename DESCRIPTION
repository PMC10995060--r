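Package: ocgraft
Title: Image-Based Finite Element Modelling of Osteochondral Graft Stability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, open pipeline for specimen-specific finite element
    assessment of the immediate (pre-osseointegration) stability of
    osteochondral grafts. Provides seeded trabecular-bone phantom generation,
    micro-CT style density processing (fixed-threshold binarisation,
    volume-conserving downsampling to bone volume fraction, linear BV/TV to
    Young's modulus mapping), structured voxel-to-tetrahedron meshing, a
    quasi-static finite element engine with linear elastic bone, compressible
    neo-Hookean cartilage and penalty Coulomb frictional contact, virtual
    compression, graft push-in and tibiofemoral joint experiments,
    calibration by stiffness RMS error and Lin's concordance correlation,
    and sensel-grid contact pressure map analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    RNifti
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
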