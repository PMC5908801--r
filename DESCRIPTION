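Package: blockrec
Title: Block-Based Single-Particle Cryo-EM Reconstruction with Ewald Sphere Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting the Ewald sphere (depth-of-field) effect in
    single-particle cryo-electron microscopy reconstructions of large objects.
    Implements a depth-of-field image simulator that applies a distinct contrast
    transfer function to thin layers of the object along the beam axis, a
    Thon-ring defocus fitter, direct Fourier-inversion reconstruction with
    Fourier shell correlation read-outs, the empirical resolution-limit formula
    for thick specimens, and a block-based reconstruction pipeline: the object
    is split into blocks, each block is reconstructed with its own local mean
    defocus derived from the particle orientation, per-particle defocus is
    refined by a cooperative multi-block phase-residual search, and the blocks
    are reassembled in real space with optional point-group symmetrisation.
    Volumes and image stacks are read and written in MRC2014 format and
    particle metadata in a STAR-dialect text table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
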