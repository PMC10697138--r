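# Independent oracles used across test files. These deliberately avoid the
# package's solver internals: the reduced root problem is solved by plain
# bisection on a hand-written conservation function.

# Multivalent equilibrium with the IL-13Ra1 chain absent (R_13 = 0):
# eliminate r_g analytically and bisect the alpha-chain conservation
# identity on [0, Ra].
oracle_typeI_no13 <- function(Ra, Rg, Ka_a, Ka_g, L, kx) {
  rg_of <- function(ra) Rg / (1 + Ka_g * L + kx * Ka_a * Ka_g * L * ra)
  f <- function(ra) ra * (1 + Ka_a * L * (1 + kx * Ka_g * rg_of(ra))) - Ra
  lo <- 0; hi <- Ra
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  ra <- (lo + hi) / 2
  rg <- rg_of(ra)
  list(r_a = ra, r_g = rg, typeI = kx * Ka_a * Ka_g * L * ra * rg)
}

# Same reduction with the gamma chain absent (R_g = 0), type II complex.
oracle_typeII_nogamma <- function(Ra, R13, Ka_a, Ka_13, L, kx) {
  out <- oracle_typeI_no13(Ra, R13, Ka_a, Ka_13, L, kx)
  list(r_a = out$r_a, r_13 = out$r_g, typeII = out$typeI)
}

# Closed-form log-dose integral of the variable-slope logistic
# y = bottom + (top - bottom) / (1 + (ec50/x)^h), u = log10 x.
logistic_auc_analytic <- function(bottom, top, ec50, h, dose_min, dose_max) {
  F <- function(u) bottom * u +
    (top - bottom) / (h * log(10)) * log1p(10^(h * (u - log10(ec50))))
  F(log10(dose_max)) - F(log10(dose_min))
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.xmin)
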