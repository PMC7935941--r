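Package: rascleave
Title: Progress-Curve Kinetics of Conformation-Selective RAS Proteolysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and global fitting of progress-curve kinetics for
    engineered, cofactor-dependent subtilisin proteases that preferentially
    cleave the active (GTP-loaded) conformation of RAS. Implements a minimal
    cleavage mechanism with reporter-substrate competition and competitive
    product inhibition, rapid-equilibrium and full mass-action simulation of
    fluorogenic (AMC) progress curves, a synthetic assay generator emulating
    RAS and product-fragment titrations, staged global estimation of the
    binding constant K_S, acylation rate k_2, product dissociation constant
    K_P and reporter specificity constant, profile-likelihood intervals for
    the specificity constant k_2/K_S, selectivity-ratio analysis, saturable
    cofactor-activation curves with a two-state conformational linkage model,
    and a cellular turnover model of synthesis, GTP hydrolysis and
    conformation-selective cleavage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
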