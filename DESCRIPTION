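Package: aakdyn
Title: Coarse-Grained Dynamics and Allosteric Communication of Amino Acid
    Kinases
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Elastic-network normal mode analysis (Gaussian and anisotropic
    network models) of protein structures at alpha-carbon resolution, with
    tools to compare intrinsic modes against crystallographic conformational
    changes (correlation cosines and cumulative overlaps), a Markov model of
    intramolecular communication built on heavy-atom contact affinities
    (hitting and commute times, optimal signalling pathways), and subsystem
    normal mode analysis through an effective (Schur-complement) Hessian for
    comparing slow modes across protein-family members. Includes
    deterministic generators of toy structures with known hinges and
    deformations so every stage can be validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
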