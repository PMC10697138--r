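#' Background-subtract and normalize dose-response measurements
#'
#' Applies the standard flow-cytometry normalization for pSTAT6 panels:
#' subtract the unstimulated background, then divide by the background-
#' subtracted mean response of a reference condition (typically the natural
#' cytokine at a saturating dose), so the reference maps to mean 1.0. The
#' normalization is applied per cell type; every cell type must contain the
#' reference condition.
#'
#' @param data data.frame with columns `cell_type`, `ligand`, `dose_molar`,
#'   `replicate`, `response` (and optionally `treatment`).
#' @param reference_ligand,reference_dose the reference condition; replicates
#'   at that condition define the per-cell-type scale.
#' @param background scalar background (unstimulated) response, same units as
#'   `response`; subtracted before scaling.
#' @param dose_tol relative tolerance for matching `reference_dose`.
#' @return `data` with `response` replaced by the normalized value.
#' @export
normalize_responses <- function(data, reference_ligand, reference_dose,
                                background = 0, dose_tol = 1e-6) {
  req <- c("cell_type", "ligand", "dose_molar", "response")
  if (!all(req %in% names(data)))
    stop("data must have columns: ", paste(req, collapse = ", "))
  out <- data
  for (ct in unique(data$cell_type)) {
    rows <- data$cell_type == ct
    ref <- rows & data$ligand == reference_ligand &
      abs(data$dose_molar - reference_dose) <= dose_tol * reference_dose
    if (!any(ref))
      stop(sprintf("cell type '%s' has no reference condition (%s at %.3g M)",
                   ct, reference_ligand, reference_dose))
    scale <- mean(data$response[ref]) - background
    if (scale <= 0)
      stop(sprintf("cell type '%s': reference response does not exceed background", ct))
    out$response[rows] <- (data$response[rows] - background) / scale
  }
  out
}

.hill_curve <- function(x, bottom, top, ec50, slope) {
  bottom + (top - bottom) / (1 + (ec50 / x)^slope)
}

#' Fit a variable-slope logistic (Hill) dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (ec50/x)^slope)`,
#' the "[agonist] vs. normalized response -- variable slope" model. EC50 is
#' optimized in log10 space with bounds two decades beyond the dose range;
#' the Hill slope is constrained to (0.1, 10). By default the bottom is fixed
#' at 0, appropriate after background subtraction.
#'
#' The fit is flagged unconverged when the optimizer fails, when the data are
#' flat within the noise floor, or when the fitted EC50 falls more than
#' 100-fold outside the dose range.
#'
#' @param dose molar concentrations (> 0), >= 4 distinct values.
#' @param response response values (one per dose entry; replicates allowed as
#'   repeated doses).
#' @param fix_bottom_to_zero fix the lower asymptote at 0 (default TRUE).
#' @return An object of class `hill_fit` with fields `bottom`, `top`, `ec50`
#'   (molar; `NA` when unconverged/degenerate), `slope`, `converged`,
#'   `residual_sse`, `n`.
#' @export
fit_hill <- function(dose, response, fix_bottom_to_zero = TRUE) {
  if (length(dose) != length(response)) stop("dose and response lengths differ")
  ok <- is.finite(dose) & is.finite(response)
  dose <- dose[ok]; response <- response[ok]
  if (any(dose <= 0)) stop("doses must be > 0 (zero-dose points are background, not fit points)")
  if (length(unique(dose)) < 4L) stop("need >= 4 distinct doses")

  lo_e <- log10(min(dose)) - 2; hi_e <- log10(max(dose)) + 2
  rng <- diff(range(response))
  degenerate <- rng <= 1e-12 * max(abs(response), 1)
  if (degenerate) {
    return(structure(list(bottom = if (fix_bottom_to_zero) 0 else mean(response),
                          top = mean(response), ec50 = NA_real_, slope = NA_real_,
                          converged = FALSE,
                          residual_sse = sum((response - mean(response))^2),
                          n = length(dose)),
                     class = "hill_fit"))
  }

  # start: top/bottom from data, EC50 where the mean curve crosses half-range
  ord <- order(dose)
  ds <- dose[ord]; ys <- response[ord]
  y0 <- if (fix_bottom_to_zero) 0 else min(response)
  y1 <- max(response)
  half <- (y0 + y1) / 2
  above <- ys >= half
  e_start <- if (any(above)) log10(ds[which(above)[1]]) else log10(stats::median(ds))
  e_start <- min(max(e_start, lo_e), hi_e)

  resid_fn <- function(p) {
    if (fix_bottom_to_zero) {
      response - .hill_curve(dose, 0, p[1], 10^p[2], p[3])
    } else {
      response - .hill_curve(dose, p[4], p[1], 10^p[2], p[3])
    }
  }
  p0 <- c(y1, e_start, 1)
  lower <- c(-Inf, lo_e, 0.1); upper <- c(Inf, hi_e, 10)
  if (!fix_bottom_to_zero) {
    p0 <- c(p0, y0); lower <- c(lower, -Inf); upper <- c(upper, Inf)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(bottom = y0, top = y1, ec50 = NA_real_, slope = NA_real_,
                          converged = FALSE, residual_sse = Inf, n = length(dose)),
                     class = "hill_fit"))
  }
  p <- fit$par
  bottom <- if (fix_bottom_to_zero) 0 else p[4]
  top <- p[1]; ec50 <- 10^p[2]; slope <- p[3]
  in_range <- ec50 >= min(dose) / 100 && ec50 <= max(dose) * 100
  converged <- fit$info %in% 1:4 && in_range && top > bottom
  structure(list(bottom = bottom, top = top, ec50 = ec50, slope = slope,
                 converged = converged,
                 residual_sse = sum(fit$fvec^2), n = length(dose)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 = %.4g M, slope = %.3g, top = %.4g, bottom = %.4g (%s, SSE %.3g)\n",
              x$ec50, x$slope, x$top, x$bottom,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$residual_sse))
  invisible(x)
}

#' Fold loss in potency between two converged dose-response fits
#'
#' @param fit_a,fit_b converged [fit_hill()] results; the ratio is
#'   `ec50_b / ec50_a`, so values > 1 mean `b` is less potent.
#' @return dimensionless ratio.
#' @export
fold_potency <- function(fit_a, fit_b) {
  for (f in list(fit_a, fit_b))
    if (!inherits(f, "hill_fit") || !isTRUE(f$converged))
      stop("fold_potency requires two converged hill_fit objects")
  fit_b$ec50 / fit_a$ec50
}

#' Fold difference between two dissociation constants
#'
#' @param kd_a,kd_b dissociation constants in molar (> 0); returns
#'   `kd_b / kd_a` (> 1 means `b` binds more weakly).
#' @return dimensionless ratio.
#' @export
fold_affinity <- function(kd_a, kd_b) {
  if (!is.numeric(kd_a) || !is.numeric(kd_b) || kd_a <= 0 || kd_b <= 0)
    stop("Kd values must be positive")
  kd_b / kd_a
}

#' Area under a fitted dose-response curve on the log10-dose axis
#'
#' Integrates the fitted logistic over `log10(dose)` between the bounds by
#' 64-node Gauss-Legendre quadrature. Used to summarize each replicate's
#' response to each ligand into one number for the response-profile PCA.
#'
#' @param fit a converged [fit_hill()] result.
#' @param dose_min,dose_max integration bounds in molar (0 < min < max).
#' @return dimensionless area (response units x decades).
#' @export
auc_log_dose <- function(fit, dose_min, dose_max) {
  if (!inherits(fit, "hill_fit") || !isTRUE(fit$converged))
    stop("auc_log_dose requires a converged hill_fit")
  if (!(dose_min > 0 && dose_max > dose_min))
    stop("need 0 < dose_min < dose_max")
  gl <- pracma::gaussLegendre(64, log10(dose_min), log10(dose_max))
  sum(gl$w * .hill_curve(10^gl$x, fit$bottom, fit$top, fit$ec50, fit$slope))
}

#' Concentration achieving a fraction of a reference maximal response
#'
#' Inverts the fitted logistic in closed form to find the dose at which the
#' curve reaches `fraction * reference_top` (e.g., the concentration giving
#' 10% of the maximal natural-cytokine activation, [C]10%). The target must
#' lie strictly between the fit's bottom and top.
#'
#' @param fit a converged [fit_hill()] result.
#' @param fraction target fraction in (0, 1).
#' @param reference_top reference maximal response (same units as the fit);
#'   defaults to the fit's own top.
#' @return dose in molar.
#' @export
conc_at_fraction <- function(fit, fraction, reference_top = fit$top) {
  if (!inherits(fit, "hill_fit") || !isTRUE(fit$converged))
    stop("conc_at_fraction requires a converged hill_fit")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  target <- fraction * reference_top
  if (!(target > fit$bottom && target < fit$top))
    stop(sprintf("unreachable level: target %.4g is outside (bottom, top) = (%.4g, %.4g)",
                 target, fit$bottom, fit$top))
  ratio <- (fit$top - fit$bottom) / (target - fit$bottom) - 1
  fit$ec50 / ratio^(1 / fit$slope)
}

#' Activity retention of a treated vs untreated cytokine preparation
#'
#' Ratio of the concentrations at which the untreated and treated curves
#' reach `fraction` of the reference maximal activation
#' (untreated / treated); 1 means full retention, values < 1 mean the
#' treated material needs proportionally more protein.
#'
#' @param fit_untreated,fit_treated converged [fit_hill()] results.
#' @inheritParams conc_at_fraction
#' @return dimensionless ratio.
#' @export
activity_retention <- function(fit_untreated, fit_treated, fraction,
                               reference_top) {
  c_un <- tryCatch(conc_at_fraction(fit_untreated, fraction, reference_top),
                   error = function(e) stop("untreated curve: ", conditionMessage(e)))
  c_tr <- tryCatch(conc_at_fraction(fit_treated, fraction, reference_top),
                   error = function(e) stop("treated curve: ", conditionMessage(e)))
  c_un / c_tr
}
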