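Package: cgnano
Title: Coarse-Grained Models of Monolayer-Protected Metal Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds simulation-ready coarse-grained models of
    monolayer-protected metal nanoparticles. Cores are carved out of
    primitive, body-centered, face-centered or hexagonally close-packed
    crystal lattices into analytic shapes (or built as hollow spherical
    shells), ligand anchors are selected by constrained distance
    maximization on the unit sphere, and two-component monolayers can be
    arranged in homogeneous, random, Janus or striped morphologies. The
    package assigns masses, elastic networks and user-supplied bonded
    parameters, writes Gromacs-dialect structure (.gro, .pdb) and
    topology (.itp, .top) files, and computes the structural statistics
    commonly used to validate such models: cumulative monolayer radial
    distributions and thickness, ligand tilt angles, radius of gyration,
    and bootstrap errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
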