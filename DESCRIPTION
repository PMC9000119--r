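Package: pacecell
Title: Pacemaking Variants of the Aliev-Panfilov and Corrado Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for two-variable phenomenological models of
    cardiac and intestinal electrophysiology in their excitable and
    pacemaking (self-oscillatory) forms: the Aliev-Panfilov model with a
    shifted cubic nullcline (pAP) and the Corrado variant of the
    Mitchell-Schaeffer model with a sigmoid gate (pCN).  Provides
    right-hand sides, nullclines and equilibrium finding; forward- and
    backward-Euler integrators with stability checking and accuracy norms;
    coupling operators for star-coupled 1D strands, anisotropic 2D grids
    with region masks, and dual-layer cylindrical sheets; action-potential
    feature extraction (POP, MDP, APD90, DI, cycle length, frequency);
    parameter sweeps and 1:1 synchronization scans; and assembled
    experiments for a 2D sinoatrial-node tissue and a 3D two-layer
    ICC-SMC intestine model with an intrinsic-frequency gradient and
    transient conduction block.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
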