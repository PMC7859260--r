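Package: helixpack
Title: Analysis of Transmembrane Helix Self-Assembly in Coarse-Grained Membrane Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the unbiased analysis of transmembrane-helix
    oligomerization in coarse-grained membrane simulations and NMR
    ensembles. Computes inter-helix residue contact matrices at
    configurable cut-offs, body-fixed radial density maps of neighbour
    helix centroids, a census of C2 dimers and C3 trimers with
    association-time statistics, Markov transition matrices over radial
    clusters, Kabsch superposition with radial/tangential/axial RMSD
    decomposition about a fitted Cn symmetry axis, and membrane
    convergence diagnostics (area per lipid, bilayer thickness). Includes
    a deterministic synthetic trajectory generator with ground-truth
    labelled planted assemblies for validation, and readers and writers
    for multi-model PDB, GRO and TRR files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    MASS,
    jsonlite,
    yaml,
    graphics,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
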