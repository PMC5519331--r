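Package: chapdock
Title: Coarse-Grained Docking and Paralog-Matched Coevolution Analysis of
    Chaperone Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing transient chaperone/cochaperone
    complexes such as Hsp70/Hsp40 (DnaK/DnaJ). Implements residue-level
    rigid-body docking with a statistical contact potential plus
    Debye-Hueckel electrostatics, sampled by replica-exchange Monte Carlo,
    with bound-ensemble extraction, dissociation-constant estimation from
    bound fractions over increasing box volumes, inertia-frame
    spherical/Euler-angle analysis, free-energy surfaces, contact
    probabilities and neighbor-count clustering into binding modes. Also
    implements inter-protein direct coupling analysis (asymmetric
    pseudo-likelihood Potts inference, Frobenius scoring, two-segment
    average-product correction, renormalized inter-protein scores) over an
    ensemble of stochastically paralog-matched paired alignments, with
    selection-frequency ranking and solvent-accessibility filtering of
    predicted contacts, plus trajectory stability metrics (inter-protein
    distance-matrix RMS and principal-axis angular deviation) and fully
    seeded synthetic-data generators with analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
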