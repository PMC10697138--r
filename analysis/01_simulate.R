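#!/usr/bin/env Rscript
# Stage 1 — generate every synthetic dataset the analysis consumes.
#
# The packaged panel configurations encode the study conditions: 5 human cell
# types x 3 ligands and 3 mouse cell types x 2 ligands, receptor abundances
# spanning type I-biased to type II-biased gamma_c:IL-13Ra1 ratios (MDM fixed
# at 381:1), BLI-derived alpha-chain Kd values, and 5% multiplicative
# measurement noise. Everything below is seeded and reproducible.

suppressMessages(library(il4model))
out <- "results/data"
seed <- 20260919L

human <- build_human_panel()
mouse <- build_mouse_panel()

message("Simulating pSTAT6 signaling panels (multivalent generator, 3 replicates, 5% noise)")
sig_h <- simulate_signaling_dataset(human, "multivalent", replicates = 3, seed = seed)
sig_m <- simulate_signaling_dataset(mouse, "multivalent", replicates = 3, seed = seed + 1)
write_csv_atomic(sig_h, file.path(out, "signaling_human.csv"))
write_csv_atomic(sig_m, file.path(out, "signaling_mouse.csv"))
write_receptor_panels(human$panels, file.path(out, "panels_human.csv"))
write_receptor_panels(mouse$panels, file.path(out, "panels_mouse.csv"))
write_affinity_table(human$affinities, file.path(out, "topology_human.csv"))
write_affinity_table(mouse$affinities, file.path(out, "topology_mouse.csv"))

message("Simulating BLI dilution series for the four printed Kd values")
bli_kds <- c(hIL4_IL4Ra = 0.48e-9, hNeo4_IL4Ra = 58e-9,
             mIL4_mIL4Ra = 3.9e-9, mNeo4_mIL4Ra = 78e-9)
bli <- do.call(rbind, lapply(names(bli_kds), function(nm) {
  traces <- simulate_bli_experiment(bli_kds[[nm]], dt = 10)
  do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(interaction = nm, trace_id = i,
               analyte_conc_molar = tr$analyte_conc,
               time_s = tr$time, signal_nm = tr$signal, phase = tr$phase)
  }))
}))
write_csv_atomic(bli, file.path(out, "bli_sensograms.csv"))

message("Simulating bead-calibration staining for every human cell type")
bead_rows <- lapply(human$panels, function(pan) simulate_bead_experiment(pan))
write_csv_atomic(bead_rows[[1]]$beads, file.path(out, "bead_standards.csv"))
write_csv_atomic(do.call(rbind, lapply(bead_rows, `[[`, "cells")),
                 file.path(out, "cell_staining.csv"))

message("Simulating qPCR Ct table and DEG gene sets")
ct <- simulate_ct_table(c(CCL17 = 4.2, CCL22 = 3.1, MMP12 = 2.5, FABP4 = -1.2),
                        n_reps = 4, noise_sd = 0.15, seed = seed + 2)
write_csv_atomic(ct, file.path(out, "qpcr_ct.csv"))
sets <- simulate_gene_sets()
write_csv_atomic(data.frame(set = rep(names(sets), lengths(sets)),
                            gene = unlist(sets, use.names = FALSE)),
                 file.path(out, "gene_sets.csv"))

message("Done: synthetic inputs under ", out)
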