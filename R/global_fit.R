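#' Configuration for global affinity fitting
#'
#' Controls the bounded trust-region least-squares optimization of the
#' log10-scale parameters: one log10 Ka per bindable ligand-receptor pair and
#' a single shared log10 Kx* across all cell types and experiments. Bounds
#' default to Ka in [1e4, 1e12] /M (Kd 1 pM - 100 uM) and Kx* in
#' [1e-15, 1e-5] M cell/receptor. Multistarts are drawn from a seeded Latin
#' hypercube over the bounds (the first start is the box center).
#'
#' @param model `"multivalent"` or `"sequential"`.
#' @param log10_ka_bounds,log10_kx_bounds numeric length-2 bounds.
#' @param multistart number of optimization starts (>= 1).
#' @param seed seed for the Latin-hypercube starts.
#' @param max_iter optimizer iteration cap per start.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(model = c("multivalent", "sequential"),
                       log10_ka_bounds = c(4, 12),
                       log10_kx_bounds = c(-15, -5),
                       multistart = 5, seed = 1, max_iter = 200) {
  model <- match.arg(model)
  stopifnot(length(log10_ka_bounds) == 2, diff(log10_ka_bounds) > 0,
            length(log10_kx_bounds) == 2, diff(log10_kx_bounds) > 0,
            multistart >= 1)
  structure(list(model = model, log10_ka_bounds = log10_ka_bounds,
                 log10_kx_bounds = log10_kx_bounds,
                 multistart = as.integer(multistart), seed = seed,
                 max_iter = max_iter),
            class = "fit_config")
}

# Free-parameter layout: element 1 is log10 Kx*; the rest are log10 Ka for
# every (ligand, receptor) pair with Ka > 0 in the topology.
.param_layout <- function(topology) {
  pairs <- do.call(rbind, lapply(topology, function(aff) {
    data.frame(ligand = aff$ligand,
               receptor = c("IL4Ra", "gamma_c", "IL13Ra1"),
               ka = c(aff$Ka_alpha, aff$Ka_gamma, aff$Ka_13),
               private = aff$private_receptor)
  }))
  pairs$free <- pairs$ka > 0
  pairs
}

.build_affinities <- function(layout, log10_ka, private_by_ligand) {
  ligs <- unique(layout$ligand)
  ka <- stats::setNames(rep(0, nrow(layout)), paste(layout$ligand, layout$receptor))
  ka[layout$free] <- 10^log10_ka
  lapply(ligs, function(lg) {
    affinity_row(lg,
                 Ka_alpha = unname(ka[paste(lg, "IL4Ra")]),
                 Ka_gamma = unname(ka[paste(lg, "gamma_c")]),
                 Ka_13 = unname(ka[paste(lg, "IL13Ra1")]),
                 private_receptor = private_by_ligand[[lg]])
  })
}

# Shared prediction engine: normalized predictions for every row of `data`.
# The per-cell-type normalization is the maximum predicted signal over the
# cell's full experimental design (`norm_grid`, defaulting to the observed
# rows themselves). Keeping the normalization grid fixed matters when fitting
# subsets (cross-validation folds): the measurement convention normalizes to
# the cell's overall maximum condition, not to whichever curves happen to be
# in the training split.
.predict_norm <- function(data, panels_by_ct, affinities, kx_star, model,
                          norm_grid = NULL) {
  cols <- c("cell_type", "ligand", "dose_molar")
  grid <- unique(rbind(data[, cols], if (!is.null(norm_grid)) norm_grid[, cols]))
  pred <- numeric(nrow(data))
  aff_by_lig <- stats::setNames(affinities, vapply(affinities, `[[`, "", "ligand"))
  for (ct in unique(data$cell_type)) {
    rows_ct <- which(data$cell_type == ct)
    g_ct <- grid[grid$cell_type == ct, , drop = FALSE]
    pan <- panels_by_ct[[ct]]
    if (is.null(pan)) stop("no receptor panel for cell type: ", ct)
    mx <- 0
    sig <- numeric(length(rows_ct))
    for (lg in unique(g_ct$ligand)) {
      aff <- aff_by_lig[[lg]]
      if (is.null(aff)) stop("no affinity topology for ligand: ", lg)
      ud <- sort(unique(g_ct$dose_molar[g_ct$ligand == lg]))
      s <- .signal_vec(ud, pan, aff, kx_star, model)
      mx <- max(mx, s)
      rws <- rows_ct[data$ligand[rows_ct] == lg]
      if (length(rws))
        sig[match(rws, rows_ct)] <- s[match(data$dose_molar[rws], ud)]
    }
    pred[rows_ct] <- if (mx > 0) sig / mx else 0
  }
  pred
}

#' Global least-squares fit of affinities and the shared crosslinking constant
#'
#' Minimizes the summed squared difference between observed and predicted
#' normalized pSTAT6 responses over every (cell type, ligand, dose,
#' replicate) point simultaneously. Predictions run the equilibrium model
#' forward and recompute the per-cell-type normalization inside every
#' objective evaluation. Pairs with Ka = 0 in the topology are fixed at no
#' binding and never enter the optimizer; one Kx* is shared by everything.
#'
#' @param data long data.frame: `cell_type`, `ligand`, `dose_molar`,
#'   `replicate`, `response` (normalized units).
#' @param panels list of [receptor_panel()] covering every cell type in
#'   `data`.
#' @param topology list of [affinity_row()] rows defining, per ligand, which
#'   receptors bind (Ka > 0 = free parameter) and the private receptor.
#' @param config a [fit_config()].
#' @param extra_starts optional list of additional parameter starting vectors
#'   (log10 scale, `c(log10_kx, log10_ka...)`), tried before the seeded
#'   starts; used by [cross_validate()] to warm-start fold refits from the
#'   full-data optimum.
#' @param norm_grid optional data.frame (`cell_type`, `ligand`, `dose_molar`)
#'   defining the full experimental design over which each cell type's
#'   normalization maximum is computed; defaults to the rows of `data`. Used
#'   when fitting subsets whose normalization convention comes from the full
#'   design (cross-validation folds).
#' @return A `global_fit` object: `log10_kx`, `kx_star`, `ka_table`
#'   (data.frame with fitted log10 Ka and Kd per pair), `fitted` (per-point
#'   observed/predicted/residual), `sse`, `accuracy` (per cell type R2),
#'   `config`, `n_starts_converged`.
#' @export
fit_global <- function(data, panels, topology, config = fit_config(),
                       extra_starts = NULL, norm_grid = NULL) {
  if (inherits(panels, "receptor_panel")) panels <- list(panels)
  if (inherits(topology, "affinity_row")) topology <- list(topology)
  req <- c("cell_type", "ligand", "dose_molar", "response")
  if (!all(req %in% names(data))) stop("data must have columns: ", paste(req, collapse = ", "))
  panels_by_ct <- stats::setNames(panels, vapply(panels, `[[`, "", "cell_type"))
  missing_pan <- setdiff(unique(data$cell_type), names(panels_by_ct))
  if (length(missing_pan)) stop("no receptor panel for: ", paste(missing_pan, collapse = ", "))

  layout <- .param_layout(topology)
  private_by_ligand <- lapply(split(layout$private, layout$ligand), `[[`, 1)
  free <- layout[layout$free, , drop = FALSE]
  if (nrow(free) == 0L) stop("topology has no bindable pairs to fit")
  unconstrained <- setdiff(unique(free$ligand), unique(data$ligand))
  if (length(unconstrained))
    warning("free parameters unconstrained by any data point (ligand ",
            paste(unconstrained, collapse = ", "), ")")

  npar <- 1L + nrow(free)
  lo <- c(config$log10_kx_bounds[1], rep(config$log10_ka_bounds[1], nrow(free)))
  hi <- c(config$log10_kx_bounds[2], rep(config$log10_ka_bounds[2], nrow(free)))

  obj <- function(p) {
    affs <- .build_affinities(layout, p[-1], private_by_ligand)
    tryCatch(
      data$response - .predict_norm(data, panels_by_ct, affs, 10^p[1],
                                    config$model, norm_grid),
      error = function(e) rep(1e3, nrow(data)))
  }

  set.seed(config$seed)
  starts <- matrix((lo + hi) / 2, nrow = 1)
  if (config$multistart > 1) {
    u <- lhs::randomLHS(config$multistart - 1L, npar)
    starts <- rbind(starts, sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))
  }
  if (!is.null(extra_starts)) {
    for (st in extra_starts) {
      if (length(st) != npar) stop("extra start of wrong length")
      starts <- rbind(pmin(pmax(st, lo), hi), starts)
    }
  }
  best <- NULL; n_ok <- 0L
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = obj, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    # info 0 = improper input; 6-8 = tolerance already satisfied beyond
    # machine limits (a usable optimum); rank all usable results by SSE
    if (is.null(fit) || fit$info == 0) next
    n_ok <- n_ok + 1L
    sse <- sum(fit$fvec^2)
    # replace the incumbent only on meaningful improvement: numerically-zero
    # optima can tie and earlier (warm) starts are preferred
    if (is.null(best) || sse < best$sse * (1 - 1e-6)) best <- list(fit = fit, sse = sse)
    if (best$sse <= 1e-16 * nrow(data)) break
  }
  if (is.null(best)) stop("global fit failed: no optimization start converged")

  p <- best$fit$par
  affs <- .build_affinities(layout, p[-1], private_by_ligand)
  pred <- .predict_norm(data, panels_by_ct, affs, 10^p[1], config$model, norm_grid)
  fitted <- data
  fitted$predicted <- pred
  fitted$residual <- data$response - pred

  ka_table <- layout[, c("ligand", "receptor")]
  ka_table$log10_ka <- NA_real_
  ka_table$log10_ka[layout$free] <- p[-1]
  ka_table$kd_molar <- ifelse(layout$free, 10^(-ka_table$log10_ka), Inf)
  ka_table$fixed_no_binding <- !layout$free

  acc <- vapply(unique(data$cell_type), function(ct) {
    r <- fitted[fitted$cell_type == ct, ]
    sst <- sum((r$response - mean(r$response))^2)
    if (sst == 0) return(NA_real_)
    1 - sum(r$residual^2) / sst
  }, numeric(1))

  structure(list(log10_kx = p[1], kx_star = 10^p[1], ka_table = ka_table,
                 fitted = fitted, sse = best$sse, accuracy = acc,
                 config = config, n_starts_converged = n_ok,
                 panels = panels_by_ct, topology = topology),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global %s fit: SSE %.4g, Kx* = %.3g M cell/receptor\n",
              x$config$model, x$sse, x$kx_star))
  free <- x$ka_table[!x$ka_table$fixed_no_binding, ]
  for (i in seq_len(nrow(free)))
    cat(sprintf("  %-8s %-8s Kd = %.4g M\n", free$ligand[i], free$receptor[i],
                free$kd_molar[i]))
  cat("  per-cell-type accuracy (R2):",
      paste(sprintf("%s %.3f", names(x$accuracy), x$accuracy), collapse = ", "), "\n")
  invisible(x)
}

#' Predict normalized responses from a fitted model on new points
#'
#' @param object a `global_fit`.
#' @param newdata data.frame with `cell_type`, `ligand`, `dose_molar`; the
#'   per-cell-type normalization is recomputed over the rows supplied.
#' @param ... unused.
#' @return `newdata` with a `predicted` column.
#' @export
predict.global_fit <- function(object, newdata, ...) {
  layout <- .param_layout(object$topology)
  private_by_ligand <- lapply(split(layout$private, layout$ligand), `[[`, 1)
  affs <- .build_affinities(layout, object$ka_table$log10_ka[layout$free],
                            private_by_ligand)
  newdata$predicted <- .predict_norm(newdata, object$panels, affs,
                                     object$kx_star, object$config$model)
  newdata
}

#' Prediction accuracy (coefficient of determination) for one cell type
#'
#' `R2 = 1 - SSE / SStot` over that cell type's points; returns the `NA`
#' sentinel when the observations have zero variance.
#'
#' @param result a [fit_global()] result.
#' @param cell_type cell type name (default: all, as a named vector).
#' @return numeric accuracy (<= 1), or named vector over cell types.
#' @export
accuracy <- function(result, cell_type = NULL) {
  if (!inherits(result, "global_fit")) stop("result must be a global_fit")
  if (is.null(cell_type)) return(result$accuracy)
  if (!cell_type %in% names(result$accuracy)) stop("unknown cell type: ", cell_type)
  unname(result$accuracy[cell_type])
}

#' Leave-one-curve-out cross-validation
#'
#' Each (cell type, ligand) dose-response curve is held out in turn; the
#' model is refit on the remainder and the held-out curve is predicted (the
#' cell type's normalization is recomputed over all its ligands, including
#' the held-out one) and scored by R2. Fold refits are warm-started from the
#' full-data optimum in addition to the configured multistarts. Folds that
#' would leave a ligand with
#' no constraining data are flagged, skipped and excluded from the summary
#' with a warning.
#'
#' @inheritParams fit_global
#' @param scheme only `"leave_one_curve_out"` is implemented.
#' @return list with `per_fold` (data.frame: cell_type, ligand, accuracy,
#'   flagged) and `mean_accuracy` over unflagged folds.
#' @export
cross_validate <- function(data, panels, topology, config = fit_config(),
                           scheme = "leave_one_curve_out") {
  scheme <- match.arg(scheme, "leave_one_curve_out")
  curves <- unique(data[, c("cell_type", "ligand")])
  if (nrow(curves) < 3L) stop("cross-validation needs >= 3 curves")
  fit_full <- fit_global(data, panels, topology, config)
  warm <- c(fit_full$log10_kx,
            fit_full$ka_table$log10_ka[!fit_full$ka_table$fixed_no_binding])
  res <- vector("list", nrow(curves))
  for (i in seq_len(nrow(curves))) {
    ct <- curves$cell_type[i]; lg <- curves$ligand[i]
    hold <- data$cell_type == ct & data$ligand == lg
    train <- data[!hold, , drop = FALSE]
    flagged <- !lg %in% train$ligand
    if (flagged) {
      warning(sprintf("fold (%s, %s): ligand unconstrained after holdout; fold excluded", ct, lg))
      res[[i]] <- data.frame(cell_type = ct, ligand = lg, accuracy = NA_real_,
                             flagged = TRUE)
      next
    }
    refit <- fit_global(train, panels, topology, config,
                        extra_starts = list(warm),
                        norm_grid = data[, c("cell_type", "ligand", "dose_molar")])
    # predict over the full cell-type grid so normalization is well-defined
    grid <- unique(data[data$cell_type == ct,
                        c("cell_type", "ligand", "dose_molar")])
    pred_grid <- predict(refit, grid)
    held <- data[hold, , drop = FALSE]
    key <- paste(held$ligand, held$dose_molar)
    held$predicted <- pred_grid$predicted[match(key, paste(pred_grid$ligand,
                                                           pred_grid$dose_molar))]
    sst <- sum((held$response - mean(held$response))^2)
    acc <- if (sst == 0) NA_real_ else 1 - sum((held$response - held$predicted)^2) / sst
    res[[i]] <- data.frame(cell_type = ct, ligand = lg, accuracy = acc,
                           flagged = FALSE)
  }
  per_fold <- do.call(rbind, res)
  list(per_fold = per_fold,
       mean_accuracy = mean(per_fold$accuracy[!per_fold$flagged], na.rm = TRUE))
}

#' Receptor-density sensitivity scan
#'
#' Scales one receptor's abundance on one cell type by each factor, refits
#' all free parameters, and records the mean squared error. Receptors with
#' zero abundance on the cell type are not evaluable (no scan is run).
#' A refit failure at a factor records an `NA` sentinel and the scan
#' continues.
#'
#' @inheritParams fit_global
#' @param receptor `"IL4Ra"`, `"gamma_c"` or `"IL13Ra1"`.
#' @param cell_type the cell type whose receptor abundance is perturbed.
#' @param factors positive scale factors (default 13 log-spaced over
#'   1e-2 - 1e2).
#' @return A `sensitivity_result`: `receptor`, `cell_type`, `factors`, `mse`
#'   (per factor), `baseline_mse`, `evaluable`.
#' @export
sensitivity_scan <- function(data, panels, topology, config = fit_config(),
                             receptor = c("IL4Ra", "gamma_c", "IL13Ra1"),
                             cell_type, factors = 10^seq(-2, 2, length.out = 13)) {
  receptor <- match.arg(receptor)
  if (any(factors <= 0)) stop("factors must be positive")
  if (inherits(panels, "receptor_panel")) panels <- list(panels)
  ct_names <- vapply(panels, `[[`, "", "cell_type")
  if (!cell_type %in% ct_names) stop("unknown cell type: ", cell_type)
  idx <- which(ct_names == cell_type)
  field <- switch(receptor, IL4Ra = "R_alpha_total", gamma_c = "R_gamma_total",
                  IL13Ra1 = "R_13_total")
  base_abund <- panels[[idx]][[field]]
  if (base_abund == 0) {
    return(structure(list(receptor = receptor, cell_type = cell_type,
                          factors = factors, mse = rep(NA_real_, length(factors)),
                          baseline_mse = NA_real_, evaluable = FALSE),
                     class = "sensitivity_result"))
  }
  fit0 <- fit_global(data, panels, topology, config)
  base_mse <- fit0$sse / nrow(data)
  mse <- vapply(factors, function(f) {
    pans <- panels
    pans[[idx]][[field]] <- base_abund * f
    tryCatch(fit_global(data, pans, topology, config)$sse / nrow(data),
             error = function(e) NA_real_)
  }, numeric(1))
  structure(list(receptor = receptor, cell_type = cell_type, factors = factors,
                 mse = mse, baseline_mse = base_mse, evaluable = TRUE),
            class = "sensitivity_result")
}
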