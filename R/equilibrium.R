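#' Receptor abundance panel for one cell type
#'
#' Bundles the total surface abundances of the three chains involved in IL-4
#' class signaling: IL-4Ralpha (the ligand-binding alpha chain shared by both
#' complexes), the common gamma chain (gamma_c, type I co-receptor) and
#' IL-13Ralpha1 (type II co-receptor). A total of exactly 0 encodes "receptor
#' not expressed / below detection".
#'
#' @param cell_type character scalar naming the cell type.
#' @param R_alpha_total,R_gamma_total,R_13_total receptors per cell (>= 0);
#'   at least one must be positive.
#' @return An object of class `receptor_panel`.
#' @export
receptor_panel <- function(cell_type, R_alpha_total, R_gamma_total, R_13_total) {
  tot <- c(R_alpha_total, R_gamma_total, R_13_total)
  if (length(tot) != 3L || anyNA(tot) || !is.numeric(tot))
    stop("receptor totals must be three non-missing numbers")
  if (any(tot < 0)) stop("receptor totals must be >= 0")
  if (all(tot == 0)) stop("at least one receptor total must be > 0")
  structure(list(cell_type = as.character(cell_type),
                 R_alpha_total = R_alpha_total,
                 R_gamma_total = R_gamma_total,
                 R_13_total = R_13_total),
            class = "receptor_panel")
}

#' @export
print.receptor_panel <- function(x, ...) {
  cat(sprintf("Receptor panel: %s\n  IL-4Ra    %10.4g /cell\n  gamma_c   %10.4g /cell\n  IL-13Ra1  %10.4g /cell\n",
              x$cell_type, x$R_alpha_total, x$R_gamma_total, x$R_13_total))
  invisible(x)
}

#' Ligand affinity row (solution association constants)
#'
#' Solution association constants Ka (1/molar) of one ligand for each receptor
#' chain. Ka = 0 encodes "no binding" exactly (not a small number); such pairs
#' are excluded from fitting and never form complexes. The private receptor is
#' the chain the ligand engages first under the sequential model: IL-13Ralpha1
#' for IL-13-class ligands, IL-4Ralpha for IL-4-class ligands and mimetics.
#'
#' @param ligand character scalar.
#' @param Ka_alpha,Ka_gamma,Ka_13 association constants, 1/molar, >= 0.
#' @param private_receptor `"IL4Ra"` or `"IL13Ra1"`.
#' @return An object of class `affinity_row`.
#' @export
affinity_row <- function(ligand, Ka_alpha, Ka_gamma, Ka_13,
                         private_receptor = c("IL4Ra", "IL13Ra1")) {
  private_receptor <- match.arg(private_receptor)
  ka <- c(Ka_alpha, Ka_gamma, Ka_13)
  if (anyNA(ka) || any(ka < 0)) stop("association constants must be >= 0 and non-missing")
  structure(list(ligand = as.character(ligand), Ka_alpha = Ka_alpha,
                 Ka_gamma = Ka_gamma, Ka_13 = Ka_13,
                 private_receptor = private_receptor),
            class = "affinity_row")
}

#' Affinity row from dissociation constants
#'
#' Convenience wrapper converting Kd (molar) to Ka = 1/Kd. `NA` or `Inf`
#' Kd encodes no binding (Ka = 0).
#'
#' @inheritParams affinity_row
#' @param Kd_alpha,Kd_gamma,Kd_13 dissociation constants in molar; `NA`/`Inf`
#'   means no binding.
#' @return An object of class `affinity_row`.
#' @export
affinity_from_kd <- function(ligand, Kd_alpha, Kd_gamma, Kd_13,
                             private_receptor = c("IL4Ra", "IL13Ra1")) {
  ka <- function(kd) {
    if (is.na(kd) || is.infinite(kd)) return(0)
    if (kd <= 0) stop("Kd must be positive (use NA/Inf for no binding)")
    1 / kd
  }
  affinity_row(ligand, ka(Kd_alpha), ka(Kd_gamma), ka(Kd_13),
               private_receptor = match.arg(private_receptor))
}

## ---------------------------------------------------------------------------
## General conservation system.
##
## Free-receptor unknowns r_a, r_g, r_13 solve
##   R_a  = r_a  * (1 + sA*Ka_a*L + I1*Kx*Ka_a*Ka_g*L*r_g + I2*Kx*Ka_a*Ka_13*L*r_13)
##   R_g  = r_g  * (1 + sG*Ka_g*L + I1*Kx*Ka_a*Ka_g*L*r_a)
##   R_13 = r_13 * (1 + sD*Ka_13*L + I2*Kx*Ka_a*Ka_13*L*r_a)
## where sX in {0,1} flags which chains capture ligand from solution and
## I1/I2 flag whether the type I / type II ternary route is open. The
## multivalent model opens everything; the sequential model allows solution
## capture only on the private chain and ternary routes only through it.
## Detailed balance makes the ternary terms path-independent, so both models
## share one solver. Solved by damped fixed-point iteration (vectorized over
## doses), with a log-space Newton fallback for stragglers.
## ---------------------------------------------------------------------------

.eq_flags <- function(affinity, model) {
  if (model == "multivalent") {
    list(sol = c(a = 1, g = 1, d = 1), t1 = 1, t2 = 1)
  } else {
    if (affinity$private_receptor == "IL4Ra") {
      list(sol = c(a = 1, g = 0, d = 0), t1 = 1, t2 = 1)
    } else {
      # IL-13-class: first bind IL-13Ra1, then IL-4Ra; no gamma_c route and
      # no solution capture by the alpha chain.
      list(sol = c(a = 0, g = 0, d = 1), t1 = 0, t2 = 1)
    }
  }
}

# Core solver: returns free-receptor vectors plus the per-dose coefficient
# vectors. Vectorized over doses; no container overhead (hot path of the
# global-fit objective).
.solve_free_receptors <- function(doses, panel, affinity, kx_star, model,
                                  tol = 1e-12, max_iter = 1e5L) {
  if (!inherits(panel, "receptor_panel")) stop("panel must be a receptor_panel")
  if (!inherits(affinity, "affinity_row")) stop("affinity must be an affinity_row")
  if (!is.numeric(kx_star) || length(kx_star) != 1L || kx_star <= 0)
    stop("Kx* must be a single positive number")
  if (any(doses < 0) || anyNA(doses)) stop("doses must be >= 0")

  fl <- .eq_flags(affinity, model)
  Ra <- panel$R_alpha_total; Rg <- panel$R_gamma_total; Rd <- panel$R_13_total
  Kaa <- affinity$Ka_alpha; Kag <- affinity$Ka_gamma; Kad <- affinity$Ka_13

  n <- length(doses)
  L <- doses
  cA <- fl$sol[["a"]] * Kaa * L          # solution capture by alpha
  cG <- fl$sol[["g"]] * Kag * L
  cD <- fl$sol[["d"]] * Kad * L
  t1 <- fl$t1 * kx_star * Kaa * Kag * L  # type I ternary coefficient
  t2 <- fl$t2 * kx_star * Kaa * Kad * L  # type II ternary coefficient

  ra <- rep(Ra, n); rg <- rep(Rg, n); rd <- rep(Rd, n)
  active <- L > 0
  if (any(active)) {
    idx <- which(active)
    xa <- ra[idx]; xg <- rg[idx]; xd <- rd[idx]
    a1 <- cA[idx]; g1 <- cG[idx]; d1 <- cD[idx]
    p1 <- t1[idx]; p2 <- t2[idx]
    converged <- FALSE
    damp <- 0.5
    # Damped iteration is marginally contractive under extreme depletion;
    # hand unconverged lanes to Newton well before the nominal budget.
    fp_budget <- min(max_iter, 3000L)
    tiny <- 1e-300
    for (it in seq_len(fp_budget)) {
      ya <- damp * xa + (1 - damp) * Ra / (1 + a1 + p1 * xg + p2 * xd)
      yg <- damp * xg + (1 - damp) * Rg / (1 + g1 + p1 * xa)
      yd <- damp * xd + (1 - damp) * Rd / (1 + d1 + p2 * xa)
      done <- all(abs(ya - xa) <= tol * ya + tiny) &&
        all(abs(yg - xg) <= tol * yg + tiny) &&
        all(abs(yd - xd) <= tol * yd + tiny)
      xa <- ya; xg <- yg; xd <- yd
      if (done) { converged <- TRUE; break }
    }
    if (!converged) {
      # residual-based retry per lane via log-space Newton
      res_a <- abs(xa * (1 + a1 + p1 * xg + p2 * xd) - Ra)
      res_g <- abs(xg * (1 + g1 + p1 * xa) - Rg)
      res_d <- abs(xd * (1 + d1 + p2 * xa) - Rd)
      bad <- which(res_a > 1e-9 * max(Ra, 1) | res_g > 1e-9 * max(Rg, 1) |
                     res_d > 1e-9 * max(Rd, 1))
      for (j in bad) {
        sol <- .newton_log_solve(Ra, Rg, Rd, a1[j], g1[j], d1[j], p1[j], p2[j])
        if (is.null(sol))
          stop(sprintf("equilibrium solver failed to converge at dose %.3g M (%s, %s model)",
                       L[idx[j]], affinity$ligand, model))
        xa[j] <- sol[1]; xg[j] <- sol[2]; xd[j] <- sol[3]
      }
    }
    ra[idx] <- xa; rg[idx] <- xg; rd[idx] <- xd
  }
  list(ra = ra, rg = rg, rd = rd, cA = cA, cG = cG, cD = cD, t1 = t1, t2 = t2,
       dose = L)
}

# Signal-only fast path: total signaling complexes (type I + type II).
.signal_vec <- function(doses, panel, affinity, kx_star, model) {
  s <- .solve_free_receptors(doses, panel, affinity, kx_star, model)
  s$t1 * s$ra * s$rg + s$t2 * s$ra * s$rd
}

# Vectorized over doses. Returns data.frame with one row per dose.
.solve_equilibrium_vec <- function(doses, panel, affinity, kx_star,
                                   model = c("multivalent", "sequential"),
                                   tol = 1e-12, max_iter = 1e5L) {
  model <- match.arg(model)
  s <- .solve_free_receptors(doses, panel, affinity, kx_star, model, tol, max_iter)
  data.frame(
    dose = s$dose,
    free_alpha = s$ra, free_gamma = s$rg, free_13 = s$rd,
    binary_alpha = s$cA * s$ra, binary_gamma = s$cG * s$rg,
    binary_13 = s$cD * s$rd,
    typeI = s$t1 * s$ra * s$rg, typeII = s$t2 * s$ra * s$rd
  )
}

# Newton iteration on u = log r for chains with positive totals; exact for
# absent chains (total 0 => free 0).
.newton_log_solve <- function(Ra, Rg, Rd, a1, g1, d1, p1, p2,
                              tol = 1e-13, max_iter = 200L) {
  tot <- c(Ra, Rg, Rd)
  on <- tot > 0
  r <- ifelse(on, tot / 2, 0)
  for (it in seq_len(max_iter)) {
    ba <- 1 + a1 + p1 * r[2] + p2 * r[3]
    bg <- 1 + g1 + p1 * r[1]
    bd <- 1 + d1 + p2 * r[1]
    f <- c(r[1] * ba - Ra, r[2] * bg - Rg, r[3] * bd - Rd)
    if (max(abs(f) / pmax(tot, 1)) < tol) return(r)
    # Jacobian wrt u = log r (dr/du = r)
    J <- rbind(
      c(r[1] * ba, r[1] * p1 * r[2], r[1] * p2 * r[3]),
      c(r[2] * p1 * r[1], r[2] * bg, 0),
      c(r[3] * p2 * r[1], 0, r[3] * bd))
    keep <- which(on)
    du <- rep(0, 3)
    step <- tryCatch(solve(J[keep, keep, drop = FALSE], -f[keep]),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    step <- pmax(pmin(step, 2), -2)   # trust region in log space
    du[keep] <- step
    r <- r * exp(du)
  }
  NULL
}

.as_equilibrium_state <- function(df_row) {
  structure(as.list(df_row), class = "equilibrium_state")
}

#' Solve the multivalent receptor-dimerization equilibrium
#'
#' The multivalent model lets a ligand bind any of its receptors from
#' solution in either order; a ligand already bound to one chain crosslinks a
#' second chain with dimensionless gain `Kx* x Ka_coreceptor x free
#' co-receptor abundance`. Ternary complexes are the signaling species:
#' type I is ligand-IL-4Ra-gamma_c, type II is ligand-IL-4Ra-IL-13Ra1; no
#' gamma_c/IL-13Ra1 co-complex exists since the ligand has a single
#' co-receptor site. Free ligand is taken equal to the dose (no depletion).
#'
#' @param dose free ligand concentration, molar (>= 0).
#' @param panel a [receptor_panel()].
#' @param affinity an [affinity_row()].
#' @param kx_star crosslinking constant Kx*, molar x cell / receptor (> 0).
#' @return An `equilibrium_state` list: free and singly-bound (binary)
#'   receptor abundances per chain, and type I / type II ternary complexes,
#'   all in receptors (complexes) per cell.
#' @export
solve_equilibrium_multivalent <- function(dose, panel, affinity, kx_star) {
  if (length(dose) != 1L) stop("dose must be a single concentration")
  .as_equilibrium_state(
    .solve_equilibrium_vec(dose, panel, affinity, kx_star, "multivalent")[1, ])
}

#' Solve the sequential (private-receptor-first) equilibrium
#'
#' The sequential model forbids solution capture by non-private chains: an
#' IL-4-class ligand must bind IL-4Ralpha first and only then recruit
#' gamma_c or IL-13Ralpha1 through the crosslinking step; an IL-13-class
#' ligand binds IL-13Ralpha1 first and then recruits IL-4Ralpha. Co-receptor
#' chains are consumed only by ternary complexes (their binary species are
#' identically zero).
#'
#' @inheritParams solve_equilibrium_multivalent
#' @return An `equilibrium_state`, as for [solve_equilibrium_multivalent()].
#' @export
solve_equilibrium_sequential <- function(dose, panel, affinity, kx_star) {
  if (length(dose) != 1L) stop("dose must be a single concentration")
  .as_equilibrium_state(
    .solve_equilibrium_vec(dose, panel, affinity, kx_star, "sequential")[1, ])
}

#' Predict normalized pSTAT6 dose-response curves for one cell type
#'
#' Predicted signal at each dose is the total abundance of signaling
#' complexes, type I + type II. Curves are normalized jointly: every ligand's
#' signal is divided by the maximum signal over all doses and all ligands of
#' the cell type, mirroring per-cell-type normalization of pSTAT6 readouts to
#' the strongest condition.
#'
#' @param doses molar concentrations (>= 1 value).
#' @param panel a [receptor_panel()].
#' @param affinities a list of [affinity_row()] objects (>= 1 ligand).
#' @param kx_star crosslinking constant, molar x cell / receptor.
#' @param model `"multivalent"` or `"sequential"`.
#' @return A list of `predicted_curve` objects with fields `cell_type`,
#'   `ligand`, `doses`, `signal` (complexes/cell) and `normalized_signal`.
#' @export
predict_curves <- function(doses, panel, affinities, kx_star,
                           model = c("multivalent", "sequential")) {
  model <- match.arg(model)
  if (length(doses) < 1L) stop("need at least one dose")
  if (inherits(affinities, "affinity_row")) affinities <- list(affinities)
  if (length(affinities) < 1L) stop("need at least one ligand")
  sig <- lapply(affinities, function(aff) {
    st <- .solve_equilibrium_vec(doses, panel, aff, kx_star, model)
    st$typeI + st$typeII
  })
  mx <- max(unlist(sig))
  lapply(seq_along(affinities), function(i) {
    s <- sig[[i]]
    structure(list(cell_type = panel$cell_type,
                   ligand = affinities[[i]]$ligand,
                   doses = doses, signal = s,
                   normalized_signal = if (mx > 0) s / mx else s * 0),
              class = "predicted_curve")
  })
}

#' Flatten predicted curves to a long data frame
#'
#' @param curves list of `predicted_curve` objects from [predict_curves()].
#' @return data.frame with columns cell_type, ligand, dose_molar, signal,
#'   normalized_signal.
#' @export
curves_to_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(cell_type = cv$cell_type, ligand = cv$ligand,
               dose_molar = cv$doses, signal = cv$signal,
               normalized_signal = cv$normalized_signal)
  }))
}
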