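Package: tunneltransit
Title: Ligand Transport Through Enzyme Tunnel Networks from MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale trajectory analysis of ligand transport through
    protein tunnel networks. Turns per-frame coordinates of a ligand and
    landmark residue groups into distance series and cavity/tunnel/bulk
    region labels, detects completed bulk-interior transits with a
    bottleneck-aware state machine and tolerance-based tie-breaking,
    unifies metastable-state ensembles across replicates via percentile
    fingerprints, PCA and HDBSCAN clustering (unified ligand states), and
    estimates binding kinetics (mean first-passage times, association and
    dissociation rates and their ratio) from Markov state models built
    with TICA, k-means microstates and spectral metastable lumping.
    Includes a synthetic-trajectory generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    igraph,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
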