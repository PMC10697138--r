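test_that("AUC-matrix PCA handles symmetry, rank-1 data and incomplete rows", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(4, 0, 1), c(2, 2, 2))
  p <- pca_responses(m)
  expect_equal(p$scores[1, ], p$scores[2, ])          # identical rows, identical scores
  expect_equal(nrow(p$scores), 4L)

  r1 <- outer(c(1, 2, 3, 5), c(0.5, 1, 2))            # rank-1 after centering
  p1 <- pca_responses(r1)
  expect_equal(p1$explained_variance[1], 1.0, tolerance = 1e-12)
  expect_true(all(diff(p1$explained_variance) <= 1e-12))

  # centering invariance: adding a constant to a column changes nothing
  shifted <- r1; shifted[, 2] <- shifted[, 2] + 100
  p2 <- pca_responses(shifted)
  expect_equal(abs(p2$scores), abs(p1$scores), tolerance = 1e-9)

  withNA <- rbind(m, c(NA, 1, 2))
  p3 <- pca_responses(withNA)
  expect_equal(p3$complete_rows, 1:4)
  expect_error(pca_responses(rbind(c(1, 2), c(NA, 1), c(2, NA), c(3, NA))), ">= 3 complete")
})

test_that("bead calibration and receptor quantification invert each other", {
  abc <- 10^seq(3, 6, length.out = 5)
  cal <- fit_bead_calibration(abc, 100 + abc, background = 100)  # slope 1, intercept 0
  expect_equal(cal$slope, 1.0, tolerance = 1e-9)
  expect_equal(cal$intercept, 0.0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1.0, tolerance = 1e-12)
  # interpolation fixed point: a bead's own MFI returns its ABC
  expect_equal(as.numeric(quantify_receptors(cal, 100 + abc[3])), abc[3], tolerance = 1e-9)
  # doubling net MFI doubles the count under slope 1
  expect_equal(as.numeric(quantify_receptors(cal, 100 + 2e4)),
               2 * as.numeric(quantify_receptors(cal, 100 + 1e4)), tolerance = 1e-9)
  # below background: sentinel, not negative
  low <- quantify_receptors(cal, 50)
  expect_true(is.na(low))
  # extrapolation beyond bead range flagged
  hi <- quantify_receptors(cal, 100 + 1e8)
  expect_true(attr(hi, "extrapolated"))
  expect_warning(fit_bead_calibration(abc, 100 + c(abc[1], 0, abc[3:5]), background = 100),
                 "non-positive net MFI")

  # round trip on random counts at zero noise
  set.seed(2)
  counts <- 10^runif(20, 2, 7)
  cal2 <- fit_bead_calibration(abc, 30 + 10^(0.2 + 0.9 * log10(abc)), background = 30)
  mfi <- 30 + 10^(0.2 + 0.9 * log10(counts))
  expect_equal(as.numeric(quantify_receptors(cal2, mfi)), counts, tolerance = 1e-8)
})

test_that("noiseless MDM staining recovers the 381:1 co-receptor ratio", {
  mdm <- build_human_panel()$panels[[3]]
  expect_equal(mdm$cell_type, "MDM")
  sim <- simulate_bead_experiment(mdm)
  cal <- fit_bead_calibration(sim$beads$ABC, sim$beads$MFI, sim$background)
  counts <- quantify_receptors(cal, sim$cells$MFI)
  names(counts) <- sim$cells$receptor
  ratio <- counts[["gamma_c"]] / counts[["IL13Ra1"]]
  expect_equal(round(ratio), 381)
})

test_that("Livak fold changes match a spreadsheet-style oracle", {
  tab <- simulate_ct_table(c(CCL17 = 3, MMP12 = -1.5), n_reps = 3)
  fc <- livak_fold_change(tab)
  # control condition: FC 1, log2 FC 0
  ctrl <- fc[fc$condition == "PBS", ]
  expect_equal(as.vector(tapply(ctrl$fold_change, ctrl$gene, mean)),
               c(1, 1), tolerance = 1e-12)
  # ddCt = -3 => FC 8
  expect_equal(as.numeric(unique(fc$fold_change[fc$condition == "treated" & fc$gene == "CCL17"])), 8)
  expect_equal(as.numeric(unique(fc$fold_change[fc$condition == "treated" & fc$gene == "MMP12"])),
               2^-1.5, tolerance = 1e-12)

  # independent naive recomputation on a randomized table
  set.seed(9)
  tab2 <- simulate_ct_table(c(g1 = 2.2, g2 = -0.7), n_reps = 4, noise_sd = 0.3, seed = 17)
  fc2 <- livak_fold_change(tab2)
  for (i in sample(nrow(fc2), 10)) {
    row <- fc2[i, ]
    ct_g <- tab2$Ct[tab2$sample == row$sample & tab2$gene == row$gene]
    ct_h <- tab2$Ct[tab2$sample == row$sample & tab2$gene == "GAPDH"]
    dct <- ct_g - ct_h
    pbs <- tab2[tab2$condition == "PBS" & tab2$gene == row$gene, ]
    ref <- mean(pbs$Ct - vapply(pbs$sample, function(s)
      tab2$Ct[tab2$sample == s & tab2$gene == "GAPDH"], numeric(1)))
    expect_equal(row$fold_change, 2^-(dct - ref), tolerance = 1e-12)
  }

  # multiplicativity: shifting all target Cts down one cycle doubles FC
  tab3 <- tab2
  tab3$Ct[tab3$gene != "GAPDH" & tab3$condition == "treated"] <-
    tab3$Ct[tab3$gene != "GAPDH" & tab3$condition == "treated"] - 1
  fc3 <- livak_fold_change(tab3)
  tr2 <- fc2$condition == "treated"
  expect_equal(fc3$fold_change[tr2], 2 * fc2$fold_change[tr2], tolerance = 1e-12)

  # summaries agree between scales
  s_a <- summarize_fold_changes(fc2)
  s_g <- summarize_fold_changes(fc2, geometric = TRUE)
  expect_equal(log2(s_g$geo_mean_fc), s_a$mean_log2_fc, tolerance = 1e-12)

  bad <- tab[tab$gene != "GAPDH", ]
  expect_error(livak_fold_change(bad), "control gene")
})

test_that("overlap summaries reproduce the cytokine DEG-sharing fractions", {
  sets <- simulate_gene_sets()
  expect_equal(unname(vapply(sets, length, integer(1))), c(966, 876, 989))
  ov <- overlap_summary(sets)
  pw <- ov$pairwise[ov$pairwise$set_a == "hIL4" & ov$pairwise$set_b == "hNeo4", ]
  expect_equal(pw$n_intersect, 805)
  expect_equal(round(100 * pw$frac_of_a), 83)
  expect_equal(ov$n_common, 798)
  expect_equal(ov$n_union, 1097)
  expect_equal(ov$common_fraction, 798 / 1097, tolerance = 1e-12)
  expect_gte(ov$common_fraction, 0.70)

  # identical sets: all fractions 1
  ident <- list(a = letters, b = letters)
  oi <- overlap_summary(ident)
  expect_equal(oi$pairwise$frac_of_a, 1.0)
  expect_equal(oi$common_fraction, 1.0)

  # symmetry and 3-set inclusion-exclusion
  expect_equal(length(intersect(sets[[1]], sets[[2]])),
               length(intersect(sets[[2]], sets[[1]])))
  sz <- ov$sizes
  pwc <- ov$pairwise$n_intersect
  expect_equal(sum(sz) - sum(pwc) + ov$n_common, ov$n_union)

  expect_warning(overlap_summary(list(a = c("x", "x", "y"), b = "y")), "deduplicated")
  expect_error(overlap_summary(list(a = letters)), ">= 2")
  expect_error(simulate_gene_sets(c(a = 10, b = 5), n_shared_all = 7), "infeasible")
})
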