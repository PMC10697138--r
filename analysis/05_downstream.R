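#!/usr/bin/env Rscript
# Stage 5 — downstream quantitation: bead-calibrated receptor counting,
# Livak qPCR fold changes, DEG-set overlap fractions, and the AUC-matrix PCA
# of signaling profiles.
#
# Expected findings: the MDM gamma_c:IL-13Ra1 ratio quantifies to 381:1; the
# hIL-4/hNeo-4 DEG sets share 83% (805 of 966); all three ligands share 798
# of 1,097 (>70%); on PC1 of the response-AUC matrix, hIL-13 profiles sit
# farther from hNeo-4 than hIL-4 does.

suppressMessages(library(il4model))

beads <- read.csv("results/data/bead_standards.csv")
cells <- read.csv("results/data/cell_staining.csv")
cal <- fit_bead_calibration(beads$ABC, beads$MFI, background = 50)
cells$receptors_per_cell <- as.numeric(quantify_receptors(cal, cells$MFI,
                                                          background = 50))
write_csv_atomic(cells, "results/tables/receptor_counts.csv")
mdm <- cells[cells$cell_type == "MDM", ]
ratio <- mdm$receptors_per_cell[mdm$receptor == "gamma_c"] /
  mdm$receptors_per_cell[mdm$receptor == "IL13Ra1"]
message(sprintf("MDM gamma_c : IL-13Ra1 = %d : 1", round(ratio)))

ct <- read.csv("results/data/qpcr_ct.csv")
fc <- livak_fold_change(ct)
write_csv_atomic(fc, "results/tables/qpcr_fold_changes.csv")
summ <- summarize_fold_changes(fc)
write_csv_atomic(summ, "results/tables/qpcr_summary.csv")
tr <- summ[summ$condition == "treated", ]
message("treated-condition log2 fold changes: ",
        paste(sprintf("%s %.2f", tr$gene, tr$mean_log2_fc), collapse = ", "))

gs <- read.csv("results/data/gene_sets.csv")
sets <- split(gs$gene, gs$set)
ov <- overlap_summary(sets)
write_csv_atomic(ov$pairwise, "results/tables/deg_overlap_pairwise.csv")
pw <- ov$pairwise[ov$pairwise$set_a == "hIL4" & ov$pairwise$set_b == "hNeo4", ]
message(sprintf("hIL-4 / hNeo-4 shared DEGs: %d of %d (%.0f%%)",
                pw$n_intersect, pw$n_a, 100 * pw$frac_of_a))
message(sprintf("three-way core: %d of %d (%.1f%%)",
                ov$n_common, ov$n_union, 100 * ov$common_fraction))

sig_h <- read.csv("results/data/signaling_human.csv")
m <- auc_matrix(sig_h)
p <- pca_responses(m)
write_csv_atomic(data.frame(profile = rownames(p$scores), p$scores),
                 "results/tables/pca_scores.csv")
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance (%d complete profiles)",
                100 * p$explained_variance[1], 100 * p$explained_variance[2],
                nrow(p$scores)))
l1 <- p$loadings[, 1]
message(sprintf("PC1 loading distances to hNeo-4: hIL-13 %.3g, hIL-4 %.3g",
                abs(l1[["hIL-13"]] - l1[["hNeo-4"]]),
                abs(l1[["hIL-4"]] - l1[["hNeo-4"]])))
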