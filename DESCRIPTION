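Package: mntrdyn
Title: Conformational Ensemble Analysis of Metallosensor Homodimer Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of homodimeric
    metal-sensing transcription factors such as Bacillus subtilis MntR.
    Reads and writes multi-model PDB trajectories, computes geometric
    activation descriptors (the inter-helix dihedral between the two
    DNA-binding helices, the linker-helix hinge angle, inter-chain Calpha
    distances, metal-site gap distances), performs gromos (Daura)
    conformational clustering on pairwise-RMSD matrices, essential-dynamics
    principal component analysis on Cartesian Calpha coordinates with
    per-residue factor loadings, and apo-versus-holo ensemble comparison.
    Includes a synthetic conformational-ensemble generator that poses a
    coarse two-chain backbone model by exact inverse geometry so that the
    descriptor distributions match prescribed targets, for testing and for
    emulating metal-bound versus metal-free simulation ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    yaml
Config/testthat/edition: 3
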