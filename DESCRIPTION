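Package: hbstrength
Title: Hydrogen-Bond Acceptor and Donor Strength Modelling from
    Quantum-Chemically Derived Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and applying machine-learned models of
    hydrogen-bond acceptor (HBA) and donor (HBD) strengths expressed as
    Gibbs free energies of 1:1 complex formation in CCl4.  Covers
    perception of HBA/HBD sites on kekulized molecular graphs, extraction
    of fourth-shell fragments with filtering, canonical-SMILES
    deduplication and MACCS/Tanimoto diversity selection, six families of
    radial atomic charge-shell descriptors, composition of reaction free
    energies from quantum-chemistry components with linear calibration
    onto experimental scales, curation filters and summary statistics for
    strength databases, Gaussian-process regression with a combined
    constant x Matern + white kernel and a predictive-variance
    applicability domain, and a synthetic fixture generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
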