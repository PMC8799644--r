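Package: restime
Title: Trajectory Analysis of Protein-Ligand Residence-Time Determinants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for explaining kinase-inhibitor residence times
    from molecular-dynamics simulations. Provides geometric protein-ligand
    interaction fingerprints (hydrogen bonds, pi-cation, pi-pi stacking, water
    bridges, salt bridges) with frame-wise frequency tables; ligand surface
    decomposition (solvent-accessible, molecular, polar and buried areas);
    per-residue sidechain solvent-exposure traces; Markov-state-model
    construction (backbone-torsion featurization, VAMP-2 scoring, TICA,
    k-means microstates, reversible transition-matrix estimation, implied
    timescales, Chapman-Kolmogorov validation, PCCA++ coarse-graining) with
    equilibrium probabilities; hydration-site clustering and displaced-water
    resolvation scoring with equilibrium-probability weighting; well-tempered
    metadynamics dissociation counting; and synthetic-data generators with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
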