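Package: tcrdom
Title: Rigid-Body Modeling of TCR Inter-Domain and TCR-pMHC Association Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-rigid-body energy minimization for predicting protein
    inter-domain association angles, specialized to the T cell receptor
    variable domains (Valpha/Vbeta) and the TCR-peptide-MHC (class I)
    orientation. Domains are reduced to oriented cuboids and moved about
    conserved centers of rotation by a BFGS driver over exponential-map
    rotation parameters, scoring poses with an OPLS-style all-atom
    nonbonded energy. Includes a standalone asparagine/glutamine
    carboxamide flip-correction tool, harmonic position restraints,
    Euler-angle orientation measurement, binding-energy ranking of
    candidate models, and deterministic synthetic fixture systems so the
    whole pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
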