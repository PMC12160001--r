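# Generators: seeded droplets, synthetic TS Hessians, analytic toy engine.

test_that("droplets are seeded, separated and correctly partitioned", {
  rx <- toy_reaction()
  cfg <- droplet_config(n_solvent = 6, seed = 11)
  a <- make_droplet(rx$structure, cfg, rx$reactive_atoms, rx$active_atoms)
  b <- make_droplet(rx$structure, cfg, rx$reactive_atoms, rx$active_atoms)
  expect_identical(a$structure$coordinates, b$structure$coordinates)

  other <- make_droplet(rx$structure,
                        droplet_config(n_solvent = 6, seed = 12),
                        rx$reactive_atoms, rx$active_atoms)
  expect_false(identical(a$structure$coordinates,
                         other$structure$coordinates))
  # the complex itself is identical across seeds (centered copy)
  expect_identical(a$structure$coordinates[1:3, ],
                   other$structure$coordinates[1:3, ])

  # n_solvent = 0 leaves the bare complex
  bare <- make_droplet(rx$structure, droplet_config(n_solvent = 0))
  expect_identical(n_atoms(bare$structure), 3L)

  # every placed solvent atom honors min_separation to other molecules
  # (the complex's own molecules may sit closer; they are not placed)
  X <- a$structure$coordinates
  mol_of <- molecule_of_atom(a$partition)
  solv_mol <- a$partition$solvent_ids
  D <- as.matrix(dist(X))
  inter <- outer(mol_of, mol_of, `!=`) &
    (outer(mol_of %in% solv_mol, mol_of %in% solv_mol, `|`))
  expect_gte(min(D[inter]), cfg$min_separation)

  # partition audit: solvent molecules have the template size
  expect_identical(length(a$partition$molecules),
                   length(a$partition$solute_ids) + 6L)
  expect_true(all(lengths(a$partition$molecules[a$partition$solvent_ids])
                  == 3L))

  # impossible packing is reported, not looped forever
  tight <- droplet_config(n_solvent = 50,
                          shell_radii = rbind(c(3, 3.5), c(3.5, 4)),
                          seed = 1, max_attempts = 20)
  expect_error(make_droplet(rx$structure, tight), "enlarge the shells")
})

test_that("synthetic TS Hessians have the prescribed spectrum and truth", {
  sys <- all_solute_system(random_atom_cloud(5, seed = 8), reactive_atoms = 1:2)
  f <- c(0.35, 0.25, 0.2, 0.15, 0.05)
  spec <- synthetic_ts_spec(sys, f, negative_eigenvalue = -0.07, seed = 21)
  made <- make_ts_hessian(spec)
  H <- made$hessian$matrix
  expect_lt(max(abs(H - t(H))), 1e-10)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), -0.07, tolerance = 1e-8)
  expect_identical(sum(ev < 0), 1L)
  # prescribed mode is an eigenvector of the assembled matrix
  expect_lt(max(abs(H %*% made$mode - (-0.07) * made$mode)), 1e-8)

  expect_error(synthetic_ts_spec(sys, f * 2), "sum to 1")

  # end-to-end recovery through the analysis chain
  ana <- analyze_modes(made$hessian, sys)
  expect_equal(unname(ana$report$c), f, tolerance = 1e-9)
  expect_identical(ana$report$involved_atoms, made$truth$involved_atoms)
})

test_that("active-solvent sets are recovered exactly from seeded Hessians", {
  # prescribed active waters with solvent amplitudes >= 1.5 c_min
  for (seed in 1:10) {
    sys <- small_droplet(n_solvent = 5, seed = seed)
    n <- n_atoms(sys$structure)
    set.seed(seed + 500)
    active_mols <- sort(sample(sys$partition$solvent_ids, 2))
    f <- rep(1e-6, n)
    f[1:3] <- c(0.30, 0.25, 0.10)         # reactive atoms; c_min = 0.10
    for (mid in active_mols)
      f[sys$partition$molecules[[mid]][1]] <- 0.15  # 1.5 x c_min
    f <- f / sum(f)
    made <- make_ts_hessian(synthetic_ts_spec(sys, f, seed = seed))
    ana <- analyze_modes(made$hessian, sys, threshold_factor = 1)
    expect_identical(ana$report$active_solvent_molecules, active_mols)
    expect_identical(ana$report$n_active, 2L)
    expect_equal(unname(ana$report$c), f, tolerance = 1e-9)
  }
})

test_that("the toy engine is analytic: finite differences and the saddle", {
  rx <- toy_reaction()
  sys <- molecular_system(rx$structure, solute_molecules = 1:2,
                          reactive_atoms = rx$reactive_atoms,
                          active_atoms = rx$active_atoms)
  # no repulsion: bonds + double well only, saddle in closed form
  eng <- toy_engine(sys, bonds = rx$bonds, dwell = rx$dwell,
                    repulsion_A = 0)

  # gradient matches central finite differences
  X <- rx$structure$coordinates + 0.05
  g <- eng$gradient(X)
  for (i in 1:3) for (c in 1:3) {
    Xp <- X; Xp[i, c] <- Xp[i, c] + 1e-6
    Xm <- X; Xm[i, c] <- Xm[i, c] - 1e-6
    expect_equal(g[i, c], (eng$energy(Xp) - eng$energy(Xm)) / 2e-6,
                 tolerance = 1e-5)
  }

  # Hessian matches finite differences of the gradient
  Hd <- eng$hessian(X)$matrix / solv_constants$bohr^2
  for (c in 1:3) {
    Xp <- X; Xp[2, c] <- Xp[2, c] + 1e-6
    Xm <- X; Xm[2, c] <- Xm[2, c] - 1e-6
    fd <- (eng$gradient(Xp) - eng$gradient(Xm)) / 2e-6
    expect_equal(Hd[3 + c, ], as.vector(t(fd)), tolerance = 1e-5)
  }

  # analytic saddle: all bonds at rest length, double well at its top
  d_OO <- 2.2; d_HA <- 1.3; d_dw <- rx$saddle_dw
  x <- (d_dw^2 - d_HA^2 + d_OO^2) / (2 * d_OO)
  Xs <- rbind(c(0, 0, 0), c(x, sqrt(d_dw^2 - x^2), 0), c(d_OO, 0, 0))
  gs <- eng$gradient(Xs)
  expect_lt(max(abs(gs)), 1e-8)
  lam <- eigen(eng$hessian(Xs)$matrix, symmetric = TRUE,
               only.values = TRUE)$values
  expect_identical(sum(lam < -1e-9), 1L)

  # internal-coordinate potential: rigid translation leaves E unchanged
  expect_equal(eng$energy(sweep(X, 2, c(3, -2, 7), `+`)), eng$energy(X),
               tolerance = 1e-12)
})

test_that("partial Hessians are the frozen-environment sub-blocks", {
  setup <- toy_trial_setup(n_solvent = 4, seed = 5)
  X <- setup$system$structure$coordinates
  full <- setup$engine$hessian(X)
  part <- setup$engine$hessian(X, atom_ids = c(1:3, 7:9))
  expect_true(part$frozen_context)
  idx <- as.vector(outer(-2:0, 3L * c(1:3, 7:9), `+`))
  expect_identical(part$matrix, full$matrix[idx, idx])
})
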