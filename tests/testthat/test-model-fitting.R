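test_that("global fit recovers generating parameters from noiseless data", {
  cfg <- small_human_config()
  dat <- simulate_signaling_dataset(cfg, "multivalent", replicates = 1, noise_sd = 0)
  fit <- fit_global(dat, cfg$panels, cfg$affinities,
                    fit_config(multistart = 3, seed = 2))
  errs <- recovery_errors(fit, cfg)
  expect_true(all(errs <= 0.5))
  expect_lt(abs(fit$log10_kx - log10(cfg$kx_star)), 0.5)
  expect_lt(fit$sse, 1e-10)
  expect_true(all(accuracy(fit) > 0.999))
  # SSE bookkeeping: reported SSE equals the sum of squared residuals
  expect_equal(fit$sse, sum(fit$fitted$residual^2), tolerance = 1e-12)
  # no-binding pairs never enter the optimizer
  nb <- fit$ka_table[fit$ka_table$fixed_no_binding, ]
  expect_true(all(is.na(nb$log10_ka)))
  expect_true(all(c("hNeo-4", "hIL-13") %in% nb$ligand))

  # objective invariance under row permutation
  set.seed(4)
  fit_perm <- fit_global(dat[sample(nrow(dat)), ], cfg$panels, cfg$affinities,
                         fit_config(multistart = 3, seed = 2))
  expect_equal(fit_perm$sse, fit$sse, tolerance = 1e-6)
})

test_that("a ligand with no signaling-capable receptor pair predicts zero everywhere", {
  cfg <- small_human_config()
  # hNeo-4's IL-13Ra1 entry is fixed no-binding: on a pure type II panel
  # (gamma_c absent) its predicted signal is identically zero
  typeII_only <- receptor_panel("typeII_only", 5000, 0, 30000)
  neo <- cfg$affinities[[3]]
  expect_identical(neo$ligand, "hNeo-4")
  sig <- il4model:::.signal_vec(cfg$doses, typeII_only, neo, cfg$kx_star, "multivalent")
  expect_true(all(sig == 0))
})

test_that("median log10 Kd recovery error stays within 0.5 under 5% noise", {
  cfg <- small_human_config()
  errs <- c()
  for (s in 1:10) {
    dat <- simulate_signaling_dataset(cfg, "multivalent", replicates = 3, seed = s)
    fit <- fit_global(dat, cfg$panels, cfg$affinities,
                      fit_config(multistart = 3, seed = s + 100))
    errs <- c(errs, recovery_errors(fit, cfg))
  }
  expect_lte(median(errs), 0.5)
})

test_that("parameters fixed at truth reproduce the generator's noise SSE", {
  cfg <- small_human_config()
  dat <- simulate_signaling_dataset(cfg, "multivalent", replicates = 6, seed = 11)
  clean <- simulate_signaling_dataset(cfg, "multivalent", replicates = 6, noise_sd = 0)
  panels_by_ct <- stats::setNames(cfg$panels, vapply(cfg$panels, `[[`, "", "cell_type"))
  pred <- il4model:::.predict_norm(dat, panels_by_ct, cfg$affinities,
                                   cfg$kx_star, "multivalent")
  expect_equal(pred, clean$response, tolerance = 1e-9)
  sse_truth <- sum((dat$response - pred)^2)
  sse_noise <- sum((dat$response - clean$response)^2)
  expect_lt(abs(sse_truth - sse_noise) / sse_noise, 0.01)
})

test_that("prediction accuracy exceeds 0.9 on nearly all packaged cell types at 5% noise", {
  acc <- c()
  for (builder in list(build_human_panel, build_mouse_panel)) {
    cfg <- builder()
    dat <- simulate_signaling_dataset(cfg, "multivalent", replicates = 3, seed = 21)
    fit <- fit_global(dat, cfg$panels, cfg$affinities,
                      fit_config(multistart = 3, seed = 22))
    acc <- c(acc, accuracy(fit))
  }
  expect_equal(length(acc), 8L)
  expect_gte(sum(acc > 0.9, na.rm = TRUE), 7L)
})

test_that("cross-validation scores near-perfect folds on noiseless data and prefers the generating model", {
  cfg <- small_human_config(n_doses = 8)
  dat <- simulate_signaling_dataset(cfg, "multivalent", replicates = 1, noise_sd = 0)
  cv_mv <- cross_validate(dat, cfg$panels, cfg$affinities,
                          fit_config("multivalent", multistart = 3, seed = 3))
  expect_equal(nrow(cv_mv$per_fold), 9L)
  expect_true(all(cv_mv$per_fold$accuracy >= 0.99, na.rm = TRUE))
  cv_seq <- cross_validate(dat, cfg$panels, cfg$affinities,
                           fit_config("sequential", multistart = 3, seed = 3))
  expect_gt(cv_mv$mean_accuracy, cv_seq$mean_accuracy)

  # nested-direction sanity on the training objective as well
  fit_mv <- fit_global(dat, cfg$panels, cfg$affinities,
                       fit_config("multivalent", multistart = 3, seed = 3))
  fit_sq <- fit_global(dat, cfg$panels, cfg$affinities,
                       fit_config("sequential", multistart = 3, seed = 3))
  expect_lte(fit_mv$sse, fit_sq$sse)

  two <- dat[dat$cell_type == "Ramos" & dat$ligand %in% c("hIL-4", "hNeo-4"), ]
  expect_error(cross_validate(two, cfg$panels, cfg$affinities), ">= 3 curves")
})

test_that("unconstrained free parameters are reported, missing panels are errors", {
  cfg <- small_human_config()
  dat <- simulate_signaling_dataset(cfg, "multivalent", replicates = 1, noise_sd = 0)
  no13 <- dat[dat$ligand != "hIL-13", ]
  expect_warning(
    fit_global(no13, cfg$panels, cfg$affinities, fit_config(multistart = 1)),
    "unconstrained")
  expect_error(fit_global(dat, cfg$panels[1:2], cfg$affinities), "no receptor panel")
})

test_that("sensitivity scan reproduces baseline at factor 1 and skips absent receptors", {
  cfg <- small_human_config(n_doses = 6)
  cfg$panels <- cfg$panels[1:2]   # Ramos + monocyte keep the scan small
  dat <- simulate_signaling_dataset(cfg, "multivalent", replicates = 1, noise_sd = 0)
  fc <- fit_config(multistart = 2, seed = 6)

  sc <- sensitivity_scan(dat, cfg$panels, cfg$affinities, fc,
                         receptor = "gamma_c", cell_type = "monocyte",
                         factors = c(0.01, 1, 100))
  expect_true(sc$evaluable)
  i1 <- which(sc$factors == 1)
  expect_lt(abs(sc$mse[i1] - sc$baseline_mse) /
              max(sc$baseline_mse, .Machine$double.eps), 1e-6)

  # myeloid-like cell: gamma_c perturbation hurts more than IL-4Ralpha
  sc_a <- sensitivity_scan(dat, cfg$panels, cfg$affinities, fc,
                           receptor = "IL4Ra", cell_type = "monocyte",
                           factors = c(0.01, 1, 100))
  i100 <- which(sc$factors == 100)
  expect_gt(sc$mse[i100], sc_a$mse[i100])

  # zero-abundance receptor: not evaluable, no refit
  pans <- cfg$panels
  pans[[2]] <- receptor_panel("monocyte", 5000, 20000, 0)
  sc_na <- sensitivity_scan(dat[dat$cell_type == "Ramos", ], pans, cfg$affinities, fc,
                            receptor = "IL13Ra1", cell_type = "monocyte",
                            factors = c(0.1, 1))
  expect_false(sc_na$evaluable)
  expect_true(all(is.na(sc_na$mse)))
})
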