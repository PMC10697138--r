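Package: il4model
Title: Equilibrium Modeling of Type I and Type II IL-4 Receptor Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic equilibrium models of IL-4 receptor complex assembly
    on cell surfaces, covering both a multivalent binding model built around a
    crosslinking constant (Kx*) and a sequential private-receptor-first model.
    Provides forward prediction of normalized pSTAT6 dose-response curves,
    global least-squares estimation of ligand-receptor affinities and a shared
    Kx* across cell types, prediction-accuracy scoring, leave-one-curve-out
    cross-validation and receptor-density sensitivity scans. Includes the
    surrounding quantitation used in cytokine-engineering studies:
    variable-slope logistic (Hill) dose-response fitting with EC50, log-dose
    AUC and fractional-activation concentrations; 1:1 Langmuir biolayer
    interferometry kinetic and equilibrium-titration fitting; bead-calibrated
    flow-cytometry receptor counting; Livak 2^-ddCt qPCR fold changes;
    gene-set overlap summaries; and PCA of signaling-response AUC matrices.
    Seeded synthetic-data generators emulate complete human and mouse
    cell-panel experiments for testing and end-to-end reproduction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
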