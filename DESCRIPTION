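Package: allodyn
Title: Dynamical Network Analysis and Allosteric Pharmacology for GPCR
    Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses molecular dynamics trajectories of G protein-coupled
    receptors and the pharmacology of their allosteric modulators. Computes
    structural descriptors (RMSD, RMSF, side-chain rotamer occupancies,
    contact and hydrogen-bond persistency), builds contact-gated dynamical
    networks weighted by the correlation of motion between residues
    (W = -log|C|), extracts optimal and suboptimal communication paths,
    edge betweenness and Girvan-Newman communities, and fits
    concentration-response data with the 3-parameter logistic equation and
    the operational model of allosterism to estimate pEC50 and the
    cooperativity Log(alpha*beta). Ships synthetic generators (harmonic
    ensembles with prescribed covariance, planted-community graphs,
    operational-model dose-response surfaces) with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    emmeans,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
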