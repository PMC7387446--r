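Package: patchylat
Title: Simulated AFM Topographs and Multiscale Interaction Models for
    Patchy-Protein 2D Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the surface self-assembly of patchy,
    C4-symmetric protein building blocks into two-dimensional crystals.
    Simulates atomic force microscopy (AFM) topographs of atomic models
    with a rigid sphere-apex/truncated-cone tip, reproducing tip
    convolution artifacts; evaluates the screened charge-dipole pair
    potential between protein-sized nanoparticles in electrolyte
    (Debye-Hueckel screening with finite-size boundary factors) and the
    resulting orientation/distance energy landscapes; constructs
    rotating-squares (auxetic) lattice geometries with p4 or p42_1 2
    plane-group dipole patterns and nearest-neighbour lattice energies;
    computes analytic electret and piezoelectric properties (polarization
    density, dipole-sheet membrane voltage) of polar lattices; and
    provides a random-adsorption null model for isolated-monomer
    coverage statistics. Includes a synthetic C4-symmetric particle
    generator for fully reproducible examples and tests, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
Suggests:
    tiff,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
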