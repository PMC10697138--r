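## CSV/JSON interfaces and the end-to-end reproduction pipeline.

# Atomic writes: write to a temp file in the target directory, then rename.
.atomic_write <- function(writer, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

#' Write a data.frame to CSV atomically
#' @param df data.frame. @param path output path.
#' @return the path, invisibly.
#' @export
write_csv_atomic <- function(df, path) {
  .atomic_write(function(tmp) utils::write.csv(df, tmp, row.names = FALSE), path)
}

#' Write an R object to JSON atomically
#' @param x object serializable by jsonlite. @param path output path.
#' @return the path, invisibly.
#' @export
write_json_atomic <- function(x, path) {
  .atomic_write(function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    path)
}

#' Read receptor panels from CSV
#'
#' Expected columns: `cell_type`, `receptor` (IL4Ra, gamma_c, IL13Ra1),
#' `receptors_per_cell`. Missing receptors count as 0 (not expressed).
#'
#' @param path CSV path.
#' @return list of [receptor_panel()] objects.
#' @export
read_receptor_panels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cell_type", "receptor", "receptors_per_cell")
  if (!all(req %in% names(df)))
    stop("receptor panel CSV needs columns: ", paste(req, collapse = ", "),
         " (file ", path, ")")
  bad <- setdiff(unique(df$receptor), c("IL4Ra", "gamma_c", "IL13Ra1"))
  if (length(bad)) stop("unknown receptor name(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  lapply(split(df, df$cell_type), function(d) {
    g <- function(r) { v <- d$receptors_per_cell[d$receptor == r]
                       if (length(v)) sum(v) else 0 }
    receptor_panel(d$cell_type[1], g("IL4Ra"), g("gamma_c"), g("IL13Ra1"))
  })
}

#' Write receptor panels to CSV
#' @param panels list of [receptor_panel()]. @param path output path.
#' @return the path, invisibly.
#' @export
write_receptor_panels <- function(panels, path) {
  df <- do.call(rbind, lapply(panels, function(p)
    data.frame(cell_type = p$cell_type,
               receptor = c("IL4Ra", "gamma_c", "IL13Ra1"),
               receptors_per_cell = c(p$R_alpha_total, p$R_gamma_total,
                                      p$R_13_total))))
  write_csv_atomic(df, path)
}

#' Read an affinity/topology table from CSV
#'
#' Expected columns: `ligand`, `receptor`, `Kd_molar` (empty = no binding),
#' `private_receptor`.
#'
#' @param path CSV path.
#' @return list of [affinity_row()] objects.
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("ligand", "receptor", "Kd_molar", "private_receptor")
  if (!all(req %in% names(df)))
    stop("affinity CSV needs columns: ", paste(req, collapse = ", "),
         " (file ", path, ")")
  lapply(split(df, df$ligand), function(d) {
    g <- function(r) { v <- d$Kd_molar[d$receptor == r]
                       if (length(v) == 0 || is.na(v[1])) NA_real_ else v[1] }
    affinity_from_kd(d$ligand[1], g("IL4Ra"), g("gamma_c"), g("IL13Ra1"),
                     private_receptor = d$private_receptor[1])
  })
}

#' Write an affinity/topology table to CSV
#' @param affinities list of [affinity_row()]. @param path output path.
#' @return the path, invisibly.
#' @export
write_affinity_table <- function(affinities, path) {
  df <- do.call(rbind, lapply(affinities, function(a)
    data.frame(ligand = a$ligand,
               receptor = c("IL4Ra", "gamma_c", "IL13Ra1"),
               Kd_molar = ifelse(c(a$Ka_alpha, a$Ka_gamma, a$Ka_13) > 0,
                                 1 / c(a$Ka_alpha, a$Ka_gamma, a$Ka_13), NA),
               private_receptor = a$private_receptor)))
  write_csv_atomic(df, path)
}

#' Fit Hill curves to every (cell type, ligand) curve of a dataset
#'
#' @param data long dose-response data.frame (`cell_type`, `ligand`,
#'   `dose_molar`, `response`; replicates pooled).
#' @param fix_bottom_to_zero passed to [fit_hill()].
#' @return data.frame: cell_type, ligand, bottom, top, ec50_molar, slope,
#'   converged, sse.
#' @export
hill_fit_table <- function(data, fix_bottom_to_zero = TRUE) {
  key <- interaction(data$cell_type, data$ligand, drop = TRUE)
  out <- do.call(rbind, lapply(split(data, key), function(d) {
    f <- fit_hill(d$dose_molar, d$response, fix_bottom_to_zero)
    data.frame(cell_type = d$cell_type[1], ligand = d$ligand[1],
               bottom = f$bottom, top = f$top, ec50_molar = f$ec50,
               slope = f$slope, converged = f$converged,
               sse = f$residual_sse)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble the replicate-level AUC matrix for response-profile PCA
#'
#' One row per (cell type, replicate) profile, one column per ligand; each
#' entry is the log-dose AUC of the Hill fit to that replicate's curve.
#' Unconverged fits yield `NA` (an incomplete profile, excluded by
#' [pca_responses()]). Integration bounds default to the smallest and largest
#' dose present anywhere in the data.
#'
#' @param data long dose-response data.frame with `replicate`.
#' @param dose_min,dose_max integration bounds in molar.
#' @return numeric matrix with rownames `cell_type.replicate`.
#' @export
auc_matrix <- function(data, dose_min = min(data$dose_molar),
                       dose_max = max(data$dose_molar)) {
  ligands <- sort(unique(data$ligand))
  key <- interaction(data$cell_type, data$replicate, drop = TRUE)
  rows <- split(data, key)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(ligands),
              dimnames = list(names(rows), ligands))
  for (i in seq_along(rows)) {
    d <- rows[[i]]
    for (lg in unique(d$ligand)) {
      dl <- d[d$ligand == lg, ]
      f <- tryCatch(fit_hill(dl$dose_molar, dl$response), error = function(e) NULL)
      if (!is.null(f) && isTRUE(f$converged))
        m[i, lg] <- auc_log_dose(f, dose_min, dose_max)
    }
  }
  m
}

.pipeline_known_keys <- c("seed", "output_dir", "species", "models",
                          "replicates", "noise_sd", "multistart",
                          "cell_types", "n_doses", "run_crossval",
                          "run_sensitivity", "sensitivity_receptor",
                          "sensitivity_cell_type", "sensitivity_factors")

#' Validate a pipeline run configuration
#'
#' Accepts a named list or a YAML file path. Unknown keys are rejected; a
#' seed is mandatory whenever the simulation noise is positive.
#'
#' @param config named list or path to a YAML file.
#' @return validated config list with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  unknown <- setdiff(names(config), .pipeline_known_keys)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(species = "human", models = c("multivalent", "sequential"),
                   replicates = 3, noise_sd = 0.05, multistart = 3,
                   cell_types = NULL, n_doses = NULL,
                   run_crossval = FALSE, run_sensitivity = FALSE,
                   sensitivity_receptor = "gamma_c",
                   sensitivity_cell_type = NULL,
                   sensitivity_factors = 10^seq(-2, 2, length.out = 13))
  config <- utils::modifyList(defaults, config)
  if (!config$species %in% c("human", "mouse")) stop("species must be human or mouse")
  if (!all(config$models %in% c("multivalent", "sequential")))
    stop("models must be multivalent and/or sequential")
  if (config$noise_sd > 0 && is.null(config$seed))
    stop("config must set a seed when noise_sd > 0")
  if (is.null(config$output_dir)) stop("config must set output_dir")
  config
}

#' Run the end-to-end reproduction pipeline
#'
#' Simulate a cell-panel signaling dataset, fit Hill curves, globally fit the
#' equilibrium model under each requested variant, score per-cell-type
#' accuracies, optionally cross-validate and run a receptor-density
#' sensitivity scan, run the AUC-matrix PCA, and write every table (CSV) and
#' the fit/provenance metadata (JSON) atomically under `output_dir`.
#'
#' @param config named list or YAML path; see [validate_run_config()].
#' @return invisibly, a list with the main in-memory results (`data`,
#'   `hill_fits`, `fits`, `cv`, `sensitivity`, `pca`, `files`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline halted at stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  out_dir <- config$output_dir
  files <- character(0)

  panel_cfg <- stage("configure", {
    pc <- if (config$species == "human") build_human_panel() else build_mouse_panel()
    if (!is.null(config$cell_types)) {
      keep <- vapply(pc$panels, `[[`, "", "cell_type") %in% config$cell_types
      if (!any(keep)) stop("no packaged cell type matches cell_types")
      pc$panels <- pc$panels[keep]
    }
    if (!is.null(config$n_doses))
      pc$doses <- max(pc$doses) / 3^seq(0, 11, length.out = config$n_doses)
    pc
  })

  data <- stage("simulate", simulate_signaling_dataset(
    panel_cfg, "multivalent", replicates = config$replicates,
    seed = config$seed, noise_sd = config$noise_sd))
  files["data"] <- write_csv_atomic(data, file.path(out_dir, "signaling_data.csv"))
  files["panels"] <- write_receptor_panels(panel_cfg$panels,
                                           file.path(out_dir, "receptor_panels.csv"))
  files["topology"] <- write_affinity_table(panel_cfg$affinities,
                                            file.path(out_dir, "affinity_topology.csv"))

  hill <- stage("fit_hill", hill_fit_table(data))
  files["hill"] <- write_csv_atomic(hill, file.path(out_dir, "hill_fits.csv"))

  fits <- list()
  for (mv in config$models) {
    fits[[mv]] <- stage(paste0("fit_binding_", mv), fit_global(
      data, panel_cfg$panels, panel_cfg$affinities,
      fit_config(mv, multistart = config$multistart,
                 seed = if (is.null(config$seed)) 1 else config$seed)))
    files[paste0("ka_", mv)] <- write_csv_atomic(
      fits[[mv]]$ka_table, file.path(out_dir, paste0("fitted_affinities_", mv, ".csv")))
  }

  cv <- NULL
  if (isTRUE(config$run_crossval)) {
    cv <- lapply(config$models, function(mv) stage(paste0("crossval_", mv),
      cross_validate(data, panel_cfg$panels, panel_cfg$affinities,
                     fit_config(mv, multistart = config$multistart,
                                seed = if (is.null(config$seed)) 1 else config$seed))))
    names(cv) <- config$models
    cv_df <- do.call(rbind, lapply(config$models, function(mv)
      cbind(model = mv, cv[[mv]]$per_fold)))
    files["cv"] <- write_csv_atomic(cv_df, file.path(out_dir, "crossval.csv"))
  }

  sens <- NULL
  if (isTRUE(config$run_sensitivity)) {
    ct <- config$sensitivity_cell_type
    if (is.null(ct)) ct <- panel_cfg$panels[[1]]$cell_type
    sens <- stage("sensitivity", sensitivity_scan(
      data, panel_cfg$panels, panel_cfg$affinities,
      fit_config(config$models[1], multistart = config$multistart,
                 seed = if (is.null(config$seed)) 1 else config$seed),
      receptor = config$sensitivity_receptor, cell_type = ct,
      factors = config$sensitivity_factors))
    files["sensitivity"] <- write_csv_atomic(
      data.frame(receptor = sens$receptor, cell_type = sens$cell_type,
                 factor = sens$factors, mse = sens$mse),
      file.path(out_dir, "sensitivity.csv"))
  }

  pca <- stage("pca", pca_responses(auc_matrix(data)))
  files["pca_scores"] <- write_csv_atomic(
    data.frame(profile = rownames(pca$scores), pca$scores),
    file.path(out_dir, "pca_scores.csv"))

  prov <- list(
    package = "il4model",
    package_version = as.character(utils::packageVersion("il4model")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[order(names(config))],
    accuracies = lapply(fits, function(f) as.list(f$accuracy)),
    kx_star = lapply(fits, `[[`, "kx_star"),
    sse = lapply(fits, `[[`, "sse"))
  files["provenance"] <- write_json_atomic(prov, file.path(out_dir, "provenance.json"))

  invisible(list(data = data, hill_fits = hill, fits = fits, cv = cv,
                 sensitivity = sens, pca = pca, files = files,
                 panel_config = panel_cfg))
}
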