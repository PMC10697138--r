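kx_default <- 1e-11

ramos_like <- receptor_panel("ramos_like", 3000, 30000, 100)
il4_like <- affinity_row("il4_like", 1 / 0.48e-9, 1 / 64e-9, 1 / 500e-9, "IL4Ra")

test_that("zero dose leaves all receptors free in both models", {
  for (solver in list(solve_equilibrium_multivalent, solve_equilibrium_sequential)) {
    st <- solver(0, ramos_like, il4_like, kx_default)
    expect_equal(st$free_alpha, 3000)
    expect_equal(st$free_gamma, 30000)
    expect_equal(st$free_13, 100)
    expect_equal(st$binary_alpha + st$binary_gamma + st$binary_13 +
                   st$typeI + st$typeII, 0)
  }
})

test_that("monovalent limit reduces to the Langmuir isotherm", {
  Ka <- 1 / 58e-9
  aff <- affinity_row("mono", Ka, 0, 0, "IL4Ra")
  pan <- receptor_panel("mono_cells", 1000, 1000, 1000)
  for (L in c(1e-10, 1 / Ka, 1e-6)) {
    st <- solve_equilibrium_multivalent(L, pan, aff, 1e-15)
    expect_equal(st$binary_alpha, 1000 * Ka * L / (1 + Ka * L), tolerance = 1e-10)
    expect_equal(st$typeI, 0)
    expect_equal(st$typeII, 0)
  }
  st_half <- solve_equilibrium_multivalent(1 / Ka, pan, aff, 1e-15)
  expect_equal(st_half$binary_alpha, 500, tolerance = 1e-10)
})

test_that("full solver matches the 1-D bisection oracle on reduced panels", {
  # fixed worked case
  pan <- receptor_panel("reduced", 1000, 1000, 0)
  aff <- affinity_row("lig", 1 / 58e-9, 1e7, 0, "IL4Ra")
  st <- solve_equilibrium_multivalent(1e-8, pan, aff, 1e-11)
  orc <- oracle_typeI_no13(1000, 1000, 1 / 58e-9, 1e7, 1e-8, 1e-11)
  expect_lt(rel_err(st$typeI, orc$typeI), 1e-6)

  # 100 random draws, alternating which co-receptor is absent
  set.seed(42)
  for (i in 1:100) {
    Ra <- 10^runif(1, 2, 5); Rc <- 10^runif(1, 2, 5)
    Ka_a <- 10^runif(1, 6, 10); Ka_c <- 10^runif(1, 5, 9)
    kx <- 10^runif(1, -13, -9); L <- 10^runif(1, -12, -6)
    if (i %% 2 == 0) {
      pan <- receptor_panel("r", Ra, Rc, 0)
      aff <- affinity_row("lig", Ka_a, Ka_c, 0, "IL4Ra")
      st <- solve_equilibrium_multivalent(L, pan, aff, kx)
      orc <- oracle_typeI_no13(Ra, Rc, Ka_a, Ka_c, L, kx)
      expect_lt(rel_err(st$typeI, orc$typeI), 1e-6)
      expect_lt(rel_err(st$free_alpha, orc$r_a), 1e-6)
    } else {
      pan <- receptor_panel("r", Ra, 0, Rc)
      aff <- affinity_row("lig", Ka_a, 0, Ka_c, "IL4Ra")
      st <- solve_equilibrium_multivalent(L, pan, aff, kx)
      orc <- oracle_typeII_nogamma(Ra, Rc, Ka_a, Ka_c, L, kx)
      expect_lt(rel_err(st$typeII, orc$typeII), 1e-6)
    }
  }
})

test_that("conservation and path symmetry hold across random full solves", {
  set.seed(7)
  for (i in 1:100) {
    Ra <- 10^runif(1, 2, 5); Rg <- 10^runif(1, 2, 5); Rd <- 10^runif(1, 2, 5)
    Ka_a <- 10^runif(1, 6, 10); Ka_g <- 10^runif(1, 5, 9); Ka_d <- 10^runif(1, 5, 9)
    kx <- 10^runif(1, -13, -9); L <- 10^runif(1, -12, -6)
    pan <- receptor_panel("r", Ra, Rg, Rd)
    aff <- affinity_row("lig", Ka_a, Ka_g, Ka_d, "IL4Ra")
    model <- if (i %% 2 == 0) solve_equilibrium_multivalent else solve_equilibrium_sequential
    st <- model(L, pan, aff, kx)
    expect_lt(rel_err(st$free_alpha + st$binary_alpha + st$typeI + st$typeII, Ra), 1e-9)
    expect_lt(rel_err(st$free_gamma + st$binary_gamma + st$typeI, Rg), 1e-9)
    expect_lt(rel_err(st$free_13 + st$binary_13 + st$typeII, Rd), 1e-9)
    # detailed balance: type I via the alpha-bound path equals the
    # gamma-bound path (multivalent only; sequential has no gamma binary)
    if (i %% 2 == 0) {
      via_alpha <- st$binary_alpha * kx * Ka_g * st$free_gamma
      via_gamma <- st$binary_gamma * kx * Ka_a * st$free_alpha
      expect_lt(rel_err(via_alpha, via_gamma), 1e-12)
      expect_lt(rel_err(via_alpha, st$typeI), 1e-12)
    }
  }
})

test_that("sequential states satisfy the private-receptor-only conservation system", {
  set.seed(11)
  for (i in 1:25) {
    Ra <- 10^runif(1, 2, 5); Rg <- 10^runif(1, 2, 5); Rd <- 10^runif(1, 2, 5)
    Ka_a <- 10^runif(1, 6, 10); Ka_g <- 10^runif(1, 5, 9); Ka_d <- 10^runif(1, 5, 9)
    kx <- 10^runif(1, -13, -9); L <- 10^runif(1, -11, -6)

    # IL-4-class: alpha private; gamma/IL-13Ra1 have no binary species and
    # are consumed only by ternary complexes
    st <- solve_equilibrium_sequential(
      L, receptor_panel("r", Ra, Rg, Rd),
      affinity_row("lig", Ka_a, Ka_g, Ka_d, "IL4Ra"), kx)
    expect_identical(st$binary_gamma, 0)
    expect_identical(st$binary_13, 0)
    ra <- st$free_alpha; rg <- st$free_gamma; rd <- st$free_13
    expect_lt(rel_err(ra * (1 + Ka_a * L * (1 + kx * Ka_g * rg + kx * Ka_d * rd)), Ra), 1e-9)
    expect_lt(rel_err(rg * (1 + kx * Ka_a * Ka_g * L * ra), Rg), 1e-9)
    expect_lt(rel_err(rd * (1 + kx * Ka_a * Ka_d * L * ra), Rd), 1e-9)

    # IL-13-class: IL-13Ra1 private, type I route closed
    st13 <- solve_equilibrium_sequential(
      L, receptor_panel("r", Ra, Rg, Rd),
      affinity_row("il13_like", Ka_a, 0, Ka_d, "IL13Ra1"), kx)
    expect_identical(st13$typeI, 0)
    expect_identical(st13$binary_alpha, 0)
    expect_gt(st13$typeII, 0)
    expect_lt(rel_err(st13$free_13 * (1 + Ka_d * L * (1 + kx * Ka_a * st13$free_alpha)), Rd), 1e-9)
  }
})

test_that("sequential ternary output is dose-monotone; multivalent hooks at high dose", {
  doses <- 10^seq(-14, -4, length.out = 61)
  pan <- receptor_panel("hook", 5000, 20000, 0)
  aff <- affinity_row("lig", 1 / 1e-9, 1 / 50e-9, 0, "IL4Ra")
  t_seq <- vapply(doses, function(L)
    solve_equilibrium_sequential(L, pan, aff, 1e-11)$typeI, numeric(1))
  t_mv <- vapply(doses, function(L)
    solve_equilibrium_multivalent(L, pan, aff, 1e-11)$typeI, numeric(1))
  expect_true(all(diff(t_seq) >= -1e-9 * max(t_seq)))
  expect_lt(t_mv[length(t_mv)], 0.5 * max(t_mv))  # hook: falls off its peak
  expect_gt(which.max(t_mv), 1)
  expect_lt(which.max(t_mv), length(t_mv))
})

test_that("normalized curves are invariant to joint receptor/Kx* rescaling", {
  doses <- 10^seq(-13, -7, length.out = 15)
  affs <- list(il4_like, affinity_row("neo4_like", 1 / 58e-9, 1 / 30e-9, 0, "IL4Ra"))
  base <- predict_curves(doses, ramos_like, affs, kx_default, "multivalent")
  for (c_scale in c(10, 0.01)) {
    pan2 <- receptor_panel("ramos_like", 3000 * c_scale, 30000 * c_scale, 100 * c_scale)
    scaled <- predict_curves(doses, pan2, affs, kx_default / c_scale, "multivalent")
    for (k in seq_along(base))
      expect_equal(scaled[[k]]$normalized_signal, base[[k]]$normalized_signal,
                   tolerance = 1e-9)
  }
})

test_that("predict_curves normalizes jointly and zeroes co-receptor-less ligands", {
  one <- predict_curves(1e-9, ramos_like, il4_like, kx_default, "multivalent")
  expect_equal(one[[1]]$normalized_signal, 1.0)

  no_co <- affinity_row("binder_only", 1 / 1e-9, 0, 0, "IL4Ra")
  cv <- predict_curves(10^seq(-12, -7, length.out = 8), ramos_like,
                       list(il4_like, no_co), kx_default, "multivalent")
  expect_true(all(cv[[2]]$signal == 0))
  expect_equal(max(c(cv[[1]]$normalized_signal, cv[[2]]$normalized_signal)), 1.0)

  df <- curves_to_df(cv)
  expect_equal(nrow(df), 16L)
  expect_setequal(unique(df$ligand), c("il4_like", "binder_only"))
})

test_that("invalid inputs are rejected", {
  expect_error(receptor_panel("x", -1, 10, 10), "must be >= 0")
  expect_error(receptor_panel("x", 0, 0, 0), "at least one")
  expect_error(affinity_row("x", -1, 0, 0, "IL4Ra"), ">= 0")
  expect_error(solve_equilibrium_multivalent(-1e-9, ramos_like, il4_like, kx_default))
  expect_error(solve_equilibrium_multivalent(1e-9, ramos_like, il4_like, 0))
})
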