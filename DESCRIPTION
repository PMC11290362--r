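Package: protgeom
Title: Differential Geometry and Knot Theory Descriptors for Protein Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits smooth parametric cubic-spline space curves through the
    C-alpha trace of a protein backbone and computes per-residue differential
    geometry descriptors (curvature, torsion, arc length) via numerically
    stable Chebyshev-series differentiation, together with the knot-theory
    writhing number over five-residue windows.  The descriptors are rigid-motion
    invariant, chirality-sensitive and metric (they satisfy the triangle
    inequality), which makes them suitable for comparing and clustering
    protein shapes.  Includes a fixed-width PDB C-alpha reader, descriptor
    annotation of PDB b-factor columns, PyMOL colouring scripts, geometric
    clustering of multiple-sequence-alignment columns into blocks of
    equivalent local geometry, environment-specific propensity table handling
    with kernel density estimates over descriptor space, a deterministic
    synthetic-fixture generator (helices, strands, circles, twisted cubics)
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pracma,
    jsonlite
Config/testthat/edition: 3
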