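Package: tmjoint
Title: Joint-Based Torsion-Angle Description of Transmembrane Helix Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained description of polytopic membrane proteins by the
    torsion angles of their transmembrane-helix joint points. The C-alpha atoms
    of the first and last residue of each membrane-spanning helix define an
    ordered joint skeleton; the signed dihedral angles over every four
    consecutive joints alternate between omega-type (helix-loop-helix, relative
    tilt of adjacent helices) and lambda-type (loop-helix-loop, side placement
    of the next-nearest helix). The package reads PDB coordinates and helix
    annotations, computes the alternating angle series, analyses angle
    distributions, consecutive sign and quadrant patterns with bootstrap
    standard deviations, screens cohorts for mirror-image lambda-sign pairs,
    and generates synthetic helix bundles with prescribed internal coordinates
    for exact round-trip validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
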