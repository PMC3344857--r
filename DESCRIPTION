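Package: scpolymer
Title: Entropy-Driven Polymer Modeling of Synaptonemal Complex Organization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models pachytene synaptonemal complexes (SCs) in the cell
    nucleus as confined, self-avoiding semiflexible polymers whose ends are
    tethered to - and diffuse along - the nuclear envelope, using lattice
    bond-fluctuation-model (BFM) Monte Carlo. Provides equilibration
    diagnostics (integrated autocorrelation time by Sokal windowing),
    conformation observables shared between simulation and reconstructed
    3D microscopy traces (squared end-to-end distance, pairwise
    center-of-mass segregation, intra- and inter-chain average crossing
    numbers via an analytic segment-pair closed form), Gaussian kernel
    density profiles of backbone density, readers and writers for
    per-nucleus SC trace stacks, a worm-like-chain synthetic trace
    generator, and sweep orchestration comparing tethered against
    untethered ensembles across bending rigidities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    readxl,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
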