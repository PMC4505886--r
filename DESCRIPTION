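Package: vdomgeom
Title: Quantitative Analysis of Immunoglobulin Variable-Domain Pairing
    Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the relative association geometry of paired
    immunoglobulin-like variable domains, developed for the Valpha/Vbeta
    domains of alpha-beta T-cell receptors. Structures are reduced to their
    variable domains, superposed onto a reference via conserved framework
    (beta-sheet core) anchor residues, and each beta-domain pose is encoded
    as a cuboid frame whose orientation is expressed as xyz-order Euler
    angles. Pairwise Euler-angle distances are clustered with Ward's
    minimum-variance method and cluster significance is assessed by
    multiscale bootstrap (approximately-unbiased and bootstrap-probability
    node support). A grid-based variance search locates the common center
    of rotation shared by all poses, and helper routines characterise its
    residue environment (interchain hydrogen bonds, conservation of the
    adjacent framework position from a multiple sequence alignment). A
    deterministic synthetic-complex generator with known ground truth
    (planted poses, pivots and cluster labels) supports end-to-end testing
    without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
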