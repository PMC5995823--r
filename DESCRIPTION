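Package: pepgrammar
Title: Random-Forest Assisted Divide-and-Conquer Search for Peptide
    Backbone Conformations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing and exploiting the statistics of peptide
    backbone phi-psi dihedral pairs ("words") in low-energy conformer
    ensembles.  Pairwise random-forest classification error rates measure
    the similarity of phi-psi distributions between units; classical
    multidimensional scaling and silhouette-guided agglomerative clustering
    group units into equivalence classes that license fragment
    substitution.  A random-forest classifier over adjacent-unit
    combinations (the "grammar") screens trial structures produced by
    splicing the conformers of two overlapping fragments, the core of a
    divide-and-conquer conformational search.  Includes an internal
    coordinate (NeRF) backbone builder, readers and writers for multi-model
    PDB, multi-frame XYZ and CSV dihedral tables, Gaussian-broadened
    density-of-states utilities, a trial-count cost model, and a synthetic
    Ramachandran-basin ensemble generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    randomForest,
    cluster,
    bio3d,
    pracma,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
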