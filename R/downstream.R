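#' PCA of a signaling-response AUC matrix
#'
#' Rows are replicate response profiles (one AUC per ligand), columns are
#' ligands. Rows with any missing ligand are excluded before the analysis
#' (profiles from cells stimulated with only a subset of ligands). Columns
#' are mean-centered but not variance-scaled: AUCs of normalized responses
#' already share a scale.
#'
#' @param mat numeric matrix (rows = replicate profiles, cols = ligands);
#'   `NA` marks missing ligand responses.
#' @param n_components number of components to return.
#' @return list with `scores` (complete rows x components), `loadings`
#'   (ligands x components), `explained_variance` (fraction per component,
#'   non-increasing), `complete_rows` (indices kept).
#' @export
pca_responses <- function(mat, n_components = 2) {
  mat <- as.matrix(mat)
  complete <- which(stats::complete.cases(mat))
  if (length(complete) < 3L)
    stop("need >= 3 complete response profiles after excluding incomplete rows")
  m <- mat[complete, , drop = FALSE]
  n_components <- min(n_components, ncol(m), nrow(m) - 1L)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       complete_rows = complete)
}

#' Fit a bead standard curve for receptor quantification
#'
#' Ordinary least squares of `log10(MFI - background)` on `log10(ABC)` over
#' the calibration bead populations (antibody binding capacity, ABC). Bead
#' kits span decades, so the fit is done on log-log scale. Beads whose net
#' MFI is not positive are dropped with a warning; a non-monotone bead series
#' triggers a warning.
#'
#' @param abc antibody binding capacities (>= 3 distinct values).
#' @param mfi measured bead MFIs.
#' @param background instrument background MFI.
#' @return A `bead_calibration`: `slope`, `intercept`, `r_squared`,
#'   `background`, `abc_range`, `mfi_range` (net, for extrapolation checks).
#' @export
fit_bead_calibration <- function(abc, mfi, background = 0) {
  if (length(abc) != length(mfi)) stop("abc and mfi lengths differ")
  net <- mfi - background
  bad <- net <= 0
  if (any(bad)) {
    warning(sum(bad), " bead(s) with non-positive net MFI dropped")
    abc <- abc[!bad]; net <- net[!bad]
  }
  if (length(unique(abc)) < 3L) stop("need >= 3 bead populations with distinct ABC")
  ord <- order(abc)
  if (any(diff(net[ord]) <= 0)) warning("bead MFIs are not monotone in ABC")
  fit <- stats::lm(log10(net) ~ log10(abc))
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("calibration slope must be positive")
  y <- log10(net)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 background = background,
                 abc_range = range(abc), mfi_range = range(net)),
            class = "bead_calibration")
}

#' Convert stained-cell MFIs to receptors per cell
#'
#' Inverts the bead calibration line: `log10(count) = (log10(MFI - background)
#' - intercept) / slope`. MFIs at or below background yield the
#' below-detection sentinel `NA` (never a negative count); queries outside
#' the calibrated bead MFI range are flagged as extrapolated.
#'
#' @param cal a [fit_bead_calibration()] result.
#' @param cell_mfi measured cell MFIs (vectorized).
#' @param background background MFI; defaults to the calibration's.
#' @return numeric vector of receptors/cell (`NA` = below detection) with a
#'   logical attribute `"extrapolated"`.
#' @export
quantify_receptors <- function(cal, cell_mfi, background = cal$background) {
  if (!inherits(cal, "bead_calibration")) stop("cal must be a bead_calibration")
  net <- cell_mfi - background
  count <- rep(NA_real_, length(net))
  ok <- net > 0
  count[ok] <- 10^((log10(net[ok]) - cal$intercept) / cal$slope)
  extrap <- ok & (net < cal$mfi_range[1] | net > cal$mfi_range[2])
  attr(count, "extrapolated") <- extrap
  count
}

#' Livak (2^-ddCt) relative-quantification fold changes
#'
#' Per sample and target gene: `dCt = Ct_gene - Ct_control_gene`;
#' `ddCt = dCt - mean(dCt over control-condition samples of that gene)`;
#' `FC = 2^-ddCt`, `log2FC = -ddCt`. Control-condition samples therefore
#' average to FC = 1 for every gene.
#'
#' @param ct data.frame with columns `sample`, `condition`, `gene`, `Ct`.
#' @param control_gene endogenous control gene (present in every sample).
#' @param control_condition the reference condition label.
#' @return data.frame: `sample`, `condition`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `log2_fc`.
#' @export
livak_fold_change <- function(ct, control_gene = "GAPDH",
                              control_condition = "PBS") {
  req <- c("sample", "condition", "gene", "Ct")
  if (!all(req %in% names(ct))) stop("ct must have columns: ", paste(req, collapse = ", "))
  if (any(!is.finite(ct$Ct))) stop("all Ct values must be finite")
  samples <- unique(ct$sample)
  ctrl_ct <- vapply(samples, function(s) {
    v <- ct$Ct[ct$sample == s & ct$gene == control_gene]
    if (length(v) == 0)
      stop(sprintf("sample '%s' has no Ct for control gene '%s'", s, control_gene))
    mean(v)
  }, numeric(1))
  names(ctrl_ct) <- samples
  tg <- ct[ct$gene != control_gene, , drop = FALSE]
  if (!any(tg$condition == control_condition))
    stop(sprintf("no samples in control condition '%s'", control_condition))
  tg$delta_ct <- tg$Ct - ctrl_ct[tg$sample]
  ref_dct <- tapply(tg$delta_ct[tg$condition == control_condition],
                    tg$gene[tg$condition == control_condition], mean)
  missing_ref <- setdiff(unique(tg$gene), names(ref_dct))
  if (length(missing_ref))
    stop("gene(s) absent from the control condition: ", paste(missing_ref, collapse = ", "))
  tg$delta_delta_ct <- tg$delta_ct - unname(ref_dct[tg$gene])
  tg$fold_change <- 2^(-tg$delta_delta_ct)
  tg$log2_fc <- -tg$delta_delta_ct
  rownames(tg) <- NULL
  tg[, c("sample", "condition", "gene", "delta_ct", "delta_delta_ct",
         "fold_change", "log2_fc")]
}

#' Summarize fold changes per condition and gene
#'
#' Arithmetic mode averages log2 fold changes (mean, sd); geometric mode
#' reports the geometric mean and geometric sd of the fold changes
#' themselves, the convention for whole-tissue qPCR panels. The two modes
#' report the same central value on different scales.
#'
#' @param fc output of [livak_fold_change()].
#' @param geometric use geometric mean/sd of FC (default: arithmetic on
#'   log2 FC).
#' @return data.frame keyed by condition and gene.
#' @export
summarize_fold_changes <- function(fc, geometric = FALSE) {
  key <- interaction(fc$condition, fc$gene, drop = TRUE)
  out <- do.call(rbind, lapply(split(fc, key), function(d) {
    if (geometric) {
      lg <- log(d$fold_change)
      data.frame(condition = d$condition[1], gene = d$gene[1], n = nrow(d),
                 geo_mean_fc = exp(mean(lg)),
                 geo_sd_fc = exp(stats::sd(lg)))
    } else {
      data.frame(condition = d$condition[1], gene = d$gene[1], n = nrow(d),
                 mean_log2_fc = mean(d$log2_fc),
                 sd_log2_fc = stats::sd(d$log2_fc))
    }
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise and k-way overlap summary of gene sets
#'
#' Exact set arithmetic on named gene-membership lists: pairwise intersection
#' counts with the shared fraction of each set (`|A n B| / |A|`), and the
#' k-way common-core fraction `|intersection of all| / |union of all|`.
#' Duplicate IDs within a set are deduplicated with a warning.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `sizes`, `pairwise` (data.frame: set_a, set_b,
#'   n_intersect, frac_of_a, frac_of_b), `n_common`, `n_union`,
#'   `common_fraction` (= n_common / n_union).
#' @export
overlap_summary <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)))
    stop("sets must be a named list of >= 2 gene vectors")
  sets <- lapply(stats::setNames(names(sets), names(sets)), function(nm) {
    g <- sets[[nm]]
    if (anyDuplicated(g)) {
      warning("duplicate gene IDs in set '", nm, "' deduplicated")
      g <- unique(g)
    }
    g
  })
  nm <- names(sets)
  k <- length(sets)
  pairs <- utils::combn(k, 2)
  pw <- do.call(rbind, apply(pairs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    ni <- length(intersect(a, b))
    data.frame(set_a = nm[ij[1]], set_b = nm[ij[2]],
               n_a = length(a), n_b = length(b), n_intersect = ni,
               frac_of_a = ni / length(a), frac_of_b = ni / length(b))
  }))
  common <- Reduce(intersect, sets)
  uni <- Reduce(union, sets)
  list(sizes = vapply(sets, length, integer(1)), pairwise = pw,
       n_common = length(common), n_union = length(uni),
       common_fraction = length(common) / length(uni))
}
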