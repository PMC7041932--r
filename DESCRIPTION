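Package: hemicam
Title: Hemiconcerted Allosteric Model of Calmodulin Signalling at the Synapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic two-state (Monod-Wyman-Changeux) model of calmodulin
    in which each lobe undergoes independent open/closed transitions, with
    explicit calcium binding, conformation-selective binding of CaMKII,
    phospho-CaMKII, calcineurin and neurogranin, ring-combinatoric CaMKII
    autophosphorylation, and calcium spike-train stimulation. Generates the
    full reaction network from the allosteric parameterization, integrates it
    with stiff ODE solvers, and derives frequency-response summaries
    (conformation AUCs, activated areas, BCM-like curves). Includes
    steady-state titration and stopped-flow chelation protocols, a synthetic
    dataset generator, and least-squares parameter recovery machinery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
NeedsCompilation: yes
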