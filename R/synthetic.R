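## Packaged study-condition constants.
##
## Receptor abundances: only the MDM gamma_c : IL-13Ra1 ratio (381:1) is an
## experimentally printed quantity; the remaining per-cell counts are
## plausible surface densities (1e2-1e5 receptors/cell) chosen once so that
## forward-simulated potencies and type I / type II bias patterns match the
## reported cell-type behavior. Alpha-chain Kd values are the reported BLI
## constants; gamma-chain ("type I complex level") Kd values were set by a
## one-time forward-simulation calibration so that the simulated reference
## cell lines reproduce the reported EC50s; Kx* was fixed at 1e-10
## molar*cell/receptor beforehand. Each constant carries a provenance note.

.human_panel_constants <- function() {
  list(
    kx_star = 1e-10,
    doses = 100e-9 / 3^(0:11),
    noise_sd = 0.05,
    panels = list(
      receptor_panel("Ramos",      3000, 30000,   100),
      receptor_panel("monocyte",   5000, 20000,  2000),
      receptor_panel("MDM",        2000, 38100,   100),
      receptor_panel("fibroblast", 3000,   300, 30000),
      receptor_panel("A549",       5000,   150, 50000)),
    affinities = list(
      affinity_from_kd("hIL-4",  0.48e-9, 6.9048164e-08, 500e-9, "IL4Ra"),
      affinity_from_kd("hIL-13", 1e-6,    NA,            3e-9,   "IL13Ra1"),
      affinity_from_kd("hNeo-4", 58e-9,   7.374375e-09,  NA,     "IL4Ra")),
    provenance = c(
      "MDM gamma_c:IL-13Ra1 = 381:1" = "measured co-receptor ratio",
      "other receptor counts" = "synthetic: plausible densities, forward-simulation calibration",
      "hIL-4 Kd_alpha 0.48 nM; hNeo-4 Kd_alpha 58 nM" = "BLI measurement",
      "hNeo-4 IL-13Ra1" = "no binding (N.B.)",
      "Kd_gamma values" = "derived: forward-simulation calibration to EC50 11 pM / 140 pM on Ramos",
      "hIL-13 Kd values; Kx*" = "synthetic: chosen, not measured"))
}

.mouse_panel_constants <- function() {
  list(
    kx_star = 1e-10,
    doses = 1e-6 / 3^(0:11),
    noise_sd = 0.05,
    panels = list(
      receptor_panel("A20",  2000, 25000,   500),
      receptor_panel("BMDM", 4000, 10000,  1000),
      receptor_panel("3T3",  3000,   500, 20000)),
    affinities = list(
      affinity_from_kd("mIL-4",  3.9e-9, 1.2403147e-07, 1e-6, "IL4Ra"),
      affinity_from_kd("mNeo-4", 78e-9,  1e-5,          NA,   "IL4Ra")),
    provenance = c(
      "mIL-4 Kd_alpha 3.9 nM; mNeo-4 Kd_alpha 78 nM" = "BLI measurement",
      "mIL-4 Kd_gamma" = "derived: forward-simulation calibration to A20 EC50 0.15 nM",
      "mNeo-4 Kd_gamma" = "synthetic: weak-binding limit (model cannot push EC50 past Kd_alpha)",
      "receptor counts; mIL-4 Kd_13; Kx*" = "synthetic: chosen, not measured"))
}

.new_panel_config <- function(constants, species) {
  structure(c(list(species = species), constants), class = "panel_config")
}

#' Packaged human cell-panel configuration
#'
#' Five human cell types (Ramos B cells, primary monocytes, monocyte-derived
#' macrophages, primary fibroblasts, A549 epithelial cells) spanning type
#' I-biased to type II-biased gamma_c : IL-13Ra1 ratios, with three ligands
#' (hIL-4, hIL-13, hNeo-4). The MDM entry carries the measured 381:1
#' co-receptor ratio; hNeo-4 has no IL-13Ra1 binding. Deterministic: two
#' calls return identical constants.
#'
#' @return A `panel_config`: `species`, `panels` (list of
#'   [receptor_panel()]), `affinities` (list of [affinity_row()]), `kx_star`,
#'   `doses` (12 threefold dilutions from 100 nM), `noise_sd` (0.05
#'   multiplicative log-normal) and `provenance` notes.
#' @export
build_human_panel <- function() .new_panel_config(.human_panel_constants(), "human")

#' Packaged mouse cell-panel configuration
#'
#' Three mouse cell types (A20 B cells, bone marrow-derived macrophages,
#' NIH/3T3 fibroblasts) with two ligands (mIL-4, mNeo-4); doses are 12
#' threefold dilutions from 1 uM.
#'
#' @return A `panel_config`, as for [build_human_panel()].
#' @export
build_mouse_panel <- function() .new_panel_config(.mouse_panel_constants(), "mouse")

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("Panel config (%s): %d cell types x %d ligands, %d doses, Kx* = %.3g, noise sd %.3g\n",
              x$species, length(x$panels), length(x$affinities),
              length(x$doses), x$kx_star, x$noise_sd))
  invisible(x)
}

#' Simulate a normalized pSTAT6 signaling dataset from a panel configuration
#'
#' Forward-simulates every (cell type, ligand, dose) combination with the
#' chosen equilibrium model, normalizes per cell type to the maximum
#' predicted signal across its ligands and doses, and applies multiplicative
#' log-normal noise independently per replicate. `noise_sd = 0` reproduces
#' [predict_curves()] exactly; identical `(config, seed)` give identical
#' output.
#'
#' @param config a `panel_config` from [build_human_panel()] /
#'   [build_mouse_panel()] (or hand-built with the same fields).
#' @param model `"multivalent"` or `"sequential"`.
#' @param replicates replicates per condition.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param noise_sd multiplicative log-normal sd; defaults to the config's.
#' @return Long data.frame: `cell_type`, `ligand`, `dose_molar`, `replicate`,
#'   `response` (normalized units).
#' @export
simulate_signaling_dataset <- function(config, model = c("multivalent", "sequential"),
                                       replicates = 3, seed = NULL,
                                       noise_sd = config$noise_sd) {
  model <- match.arg(model)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    set.seed(seed)
  }
  out <- do.call(rbind, lapply(config$panels, function(pan) {
    cv <- predict_curves(config$doses, pan, config$affinities, config$kx_star, model)
    base <- curves_to_df(cv)
    do.call(rbind, lapply(seq_len(replicates), function(rep_i) {
      resp <- base$normalized_signal
      if (noise_sd > 0) resp <- resp * exp(stats::rnorm(length(resp), 0, noise_sd))
      data.frame(cell_type = base$cell_type, ligand = base$ligand,
                 dose_molar = base$dose_molar, replicate = rep_i,
                 response = resp)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a biolayer-interferometry dilution-series experiment
#'
#' Generates a threefold dilution series of 1:1 Langmuir sensograms (900 s
#' association, 1,200 s dissociation by default). The printed study constants
#' report only Kd, so fixtures fix `k_on` and derive `k_off = k_on * kd`;
#' recovered Kd is invariant to that choice.
#'
#' @param kd dissociation constant, molar.
#' @param k_on association rate, 1/(molar x second).
#' @param r_max saturating response, nm.
#' @param top_conc,n_dilutions,dilution_factor analyte dilution series.
#' @param t_assoc,t_dissoc phase durations, seconds.
#' @param noise_sd Gaussian noise sd, nm.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @param dt sampling interval, seconds.
#' @return list of `sensogram` objects.
#' @export
simulate_bli_experiment <- function(kd, k_on = 1e5, r_max = 1.2,
                                    top_conc = 200e-9, n_dilutions = 6,
                                    dilution_factor = 3,
                                    t_assoc = 900, t_dissoc = 1200,
                                    noise_sd = 0, seed = NULL, dt = 2) {
  if (kd <= 0) stop("kd must be positive")
  if (noise_sd > 0 && is.null(seed)) stop("seed is required when noise_sd > 0")
  concs <- top_conc / dilution_factor^(0:(n_dilutions - 1))
  lapply(seq_along(concs), function(i)
    simulate_sensogram(k_on, k_on * kd, r_max, concs[i], t_assoc, t_dissoc,
                       noise_sd = noise_sd,
                       seed = if (noise_sd > 0) seed + i else NULL, dt = dt))
}

#' Simulate a bead-calibration receptor-staining experiment
#'
#' Builds a log-log-linear antibody-binding-capacity (ABC) standard curve and
#' stains the cells of a receptor panel through the same curve: net MFI =
#' `10^(intercept + slope * log10(count))`, plus the instrument background.
#'
#' @param panel a [receptor_panel()] whose three receptor counts are staged
#'   as cell MFIs.
#' @param slope,intercept calibration line on log10(MFI_net) vs log10(ABC).
#' @param background instrument background MFI added to every measurement.
#' @param abc antibody binding capacities of the bead populations.
#' @param noise_sd multiplicative log-normal sd on net MFIs (0 = noiseless).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return list with `beads` (bead_id, ABC, MFI), `cells` (cell_type,
#'   receptor, MFI) and `background`.
#' @export
simulate_bead_experiment <- function(panel, slope = 1, intercept = 0,
                                     background = 50,
                                     abc = 10^seq(3, 6, length.out = 5),
                                     noise_sd = 0, seed = NULL) {
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    set.seed(seed)
  }
  line <- function(count) 10^(intercept + slope * log10(count))
  jitter_ <- function(x) if (noise_sd > 0) x * exp(stats::rnorm(length(x), 0, noise_sd)) else x
  beads <- data.frame(bead_id = paste0("bead", seq_along(abc)), ABC = abc,
                      MFI = background + jitter_(line(abc)))
  counts <- c(IL4Ra = panel$R_alpha_total, gamma_c = panel$R_gamma_total,
              IL13Ra1 = panel$R_13_total)
  keep <- counts > 0
  cells <- data.frame(cell_type = panel$cell_type,
                      receptor = names(counts)[keep],
                      MFI = background + jitter_(line(counts[keep])))
  rownames(cells) <- NULL
  list(beads = beads, cells = cells, background = background)
}

#' Simulate a qPCR Ct table with configured fold changes
#'
#' Builds a Livak-style Ct table: an endogenous control gene with constant
#' expression, target genes at baseline Ct in the control condition, and
#' treated-condition Cts shifted by `-log2_fc` (so the intended fold change
#' is `2^log2_fc`).
#'
#' @param log2_fc named numeric vector: intended log2 fold change per target
#'   gene in the treated condition.
#' @param n_reps replicates per condition.
#' @param control_gene,control_condition,treated_condition labels.
#' @param baseline_ct target-gene Ct in the control condition.
#' @param control_ct endogenous-control Ct.
#' @param noise_sd Gaussian Ct noise (cycles); 0 = exact.
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return data.frame: `sample`, `condition`, `gene`, `Ct`.
#' @export
simulate_ct_table <- function(log2_fc, n_reps = 4, control_gene = "GAPDH",
                              control_condition = "PBS",
                              treated_condition = "treated",
                              baseline_ct = 24, control_ct = 18,
                              noise_sd = 0, seed = NULL) {
  if (is.null(names(log2_fc)) || any(names(log2_fc) == ""))
    stop("log2_fc must be a named vector of target genes")
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    set.seed(seed)
  }
  rows <- list()
  for (cond in c(control_condition, treated_condition)) {
    for (r in seq_len(n_reps)) {
      smp <- paste0(cond, "_", r)
      shift <- if (cond == treated_condition) -log2_fc else 0 * log2_fc
      ct <- c(control_ct, baseline_ct + shift)
      if (noise_sd > 0) ct <- ct + stats::rnorm(length(ct), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, condition = cond,
        gene = c(control_gene, names(log2_fc)), Ct = ct)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate gene sets with configured overlap structure
#'
#' Builds named gene sets realizing exact intersection cardinalities: all
#' sets share `n_shared_all` genes; each pair may share additional genes; the
#' rest are unique fillers. Defaults reproduce a three-cytokine
#' differential-expression overlap with |set1| = 966, |set1 n set2| = 805,
#' |all three| = 798 and |union| = 1,097.
#'
#' @param set_sizes named integer vector of total set sizes (>= 2 sets).
#' @param n_shared_all genes common to all sets.
#' @param pairwise named list of TOTAL pairwise intersection sizes (names
#'   like `"A|B"`, each >= `n_shared_all`); omitted pairs share only the
#'   common core.
#' @return named list of character vectors (gene IDs).
#' @export
simulate_gene_sets <- function(set_sizes = c(hIL4 = 966, hNeo4 = 876, hIL13 = 989),
                               n_shared_all = 798,
                               pairwise = list("hIL4|hNeo4" = 805,
                                               "hIL4|hIL13" = 898,
                                               "hNeo4|hIL13" = 829)) {
  k <- length(set_sizes)
  if (k < 2L) stop("need >= 2 sets")
  nm <- names(set_sizes)
  if (n_shared_all > min(set_sizes))
    stop("infeasible overlap: common intersection exceeds the smallest set")
  extra <- matrix(0, k, k, dimnames = list(nm, nm))
  for (key in names(pairwise)) {
    pr <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (length(pr) != 2L || !all(pr %in% nm)) stop("bad pairwise key: ", key)
    tot <- pairwise[[key]]
    if (tot < n_shared_all) stop("infeasible overlap: pairwise < common core for ", key)
    if (tot > min(set_sizes[pr])) stop("infeasible overlap: ", key, " exceeds a set size")
    extra[pr[1], pr[2]] <- extra[pr[2], pr[1]] <- tot - n_shared_all
  }
  committed <- n_shared_all + rowSums(extra)
  if (any(committed > set_sizes))
    stop("infeasible overlap: committed shared genes exceed size of set ",
         nm[which(committed > set_sizes)[1]])
  counter <- 0L
  next_genes <- function(n) {
    ids <- sprintf("gene%05d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  core <- next_genes(n_shared_all)
  sets <- stats::setNames(lapply(nm, function(x) core), nm)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (extra[i, j] > 0) {
      g <- next_genes(extra[i, j])
      sets[[nm[i]]] <- c(sets[[nm[i]]], g)
      sets[[nm[j]]] <- c(sets[[nm[j]]], g)
    }
  }
  for (i in seq_len(k)) {
    fill <- set_sizes[i] - length(sets[[nm[i]]])
    if (fill > 0) sets[[nm[i]]] <- c(sets[[nm[i]]], next_genes(fill))
  }
  sets
}
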