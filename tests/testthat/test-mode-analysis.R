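# Mass weighting, mode scoring/selection, per-atom contributions and
# active-solvent identification.

test_that("mass weighting scales per atom and renormalizes", {
  # equal masses: direction unchanged
  v <- c(1, 2, 3, 4, 5, 6)
  out <- mass_weight_and_normalize(v, c(2, 2))
  expect_equal(out, v / sqrt(sum(v^2)), tolerance = 1e-12)

  # masses (1, 16), one unit component per atom: squares split 1:256
  v2 <- c(1, 0, 0, 1, 0, 0)
  out2 <- mass_weight_and_normalize(v2, c(1, 16))
  expect_equal(sum(out2[1:3]^2), 1 / 257, tolerance = 1e-12)
  expect_equal(sum(out2[4:6]^2), 256 / 257, tolerance = 1e-12)

  set.seed(1)
  for (i in 1:5) {
    v <- rnorm(12)
    expect_equal(sum(mass_weight_and_normalize(v, runif(4, 1, 20))^2), 1,
                 tolerance = 1e-12)
  }
  expect_error(mass_weight_and_normalize(rep(0, 6), c(1, 1)), "zero mode")
})

test_that("reactive contribution is the squared amplitude on reactive atoms", {
  # localized entirely on one reactive atom
  v <- c(0, 0, 1, 0, 0, 0)
  expect_equal(reactive_contribution(v, 1L), 1)
  expect_equal(reactive_contribution(v, 2L), 0)
  # uniform over 4 atoms, 2 reactive -> 0.5
  u <- rep(1 / sqrt(12), 12)
  expect_equal(reactive_contribution(u, c(1L, 3L)), 0.5, tolerance = 1e-12)
  expect_error(reactive_contribution(v, integer(0)), "empty")
})

test_that("mode scoring selects by the weighted sum of w_norm and C", {
  # construct a mode set directly: two negative modes with known (w, C)
  # (w, C) = (-4, 0.2) and (-1, 0.9) -> s = (0.6, 0.575): first wins
  n_atoms <- 4L
  masses <- rep(1, n_atoms)
  v1 <- c(sqrt(0.2 / 2), 0, 0, sqrt(0.2 / 2), 0, 0,
          sqrt(0.8 / 2), 0, 0, sqrt(0.8 / 2), 0, 0)
  v2 <- c(0, sqrt(0.9 / 2), 0, 0, sqrt(0.9 / 2), 0,
          0, sqrt(0.1 / 2), 0, 0, sqrt(0.1 / 2), 0)
  V <- qr.Q(qr(cbind(v1, v2, matrix(rnorm(12 * 10), 12))))
  lam <- c(-4, -1, seq(1, 10, length.out = 10))
  H <- V %*% (lam * t(V))
  hd <- hessian_data((H + t(H)) / 2, 1:4)
  scores <- score_modes(mode_set(hd), masses, reactive_atoms = 1:2)
  expect_equal(sort(scores$score), c(0.575, 0.6), tolerance = 1e-9)
  sel <- attr(scores, "selected")
  expect_equal(scores$w[sel], -4, tolerance = 1e-9)
  expect_equal(scores$C[sel], 0.2, tolerance = 1e-9)

  # positive-definite Hessian: no TS character
  hd_pos <- hessian_data(diag(12), 1:4)
  expect_error(score_modes(mode_set(hd_pos), masses, 1:2), "no negative")

  # single negative eigenvalue is always selected
  lam1 <- c(-0.3, seq(0.5, 3, length.out = 11))
  H1 <- V %*% (lam1 * t(V))
  s1 <- score_modes(mode_set(hessian_data((H1 + t(H1)) / 2, 1:4)),
                    masses, 1:2)
  expect_identical(nrow(s1), 1L)
  expect_equal(s1$w_norm, 1)
})

test_that("mode scores are bounded and the dominant mode always wins", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    sys <- all_solute_system(random_atom_cloud(n, seed = i))
    f <- runif(n); f <- f / sum(f)
    spec <- synthetic_ts_spec(sys, f, seed = i)
    hd <- make_ts_hessian(spec)$hessian
    sc <- score_modes(mode_set(hd), sys$structure$masses,
                      sample(n, max(1, n %/% 2)))
    expect_true(all(sc$score >= 0 & sc$score <= 1 + 1e-12))
    expect_true(all(sc$w_norm >= 0 & sc$w_norm <= 1))
    # a mode with both w = w_min and maximal C dominates
    dom <- which(sc$w_norm == 1)
    if (sc$C[dom[1]] == max(sc$C))
      expect_equal(attr(sc, "selected"), dom[1])
  }
})

test_that("atom contributions sum to one and recover prescribed fractions", {
  expect_equal(atom_contributions(c(1, 0, 0, 1, 0, 0), c(3, 3)),
               c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(atom_contributions(c(0, 0, 0, 0.2, -0.3, 0.1), c(5, 7)),
               c(0, 1), tolerance = 1e-12)

  sys <- all_solute_system(random_atom_cloud(4, seed = 9))
  f <- c(0.4, 0.3, 0.2, 0.1)
  made <- make_ts_hessian(synthetic_ts_spec(sys, f, seed = 5))
  ana <- mode_set(made$hessian)
  c_rec <- atom_contributions(ana$vectors[, 1], sys$structure$masses)
  expect_equal(c_rec, f, tolerance = 1e-9)
  expect_equal(sum(c_rec), 1, tolerance = 1e-9)
})

test_that("involved atoms and active solvent molecules follow the c_min rule", {
  sys <- small_droplet(n_solvent = 4, seed = 3)
  n <- n_atoms(sys$structure)
  # put most weight on the reactive atoms, a clear signal on solvent
  # molecule 3 (atoms 4:6) and trace weight elsewhere
  c_at <- rep(1e-6, n)
  c_at[1:3] <- c(0.5, 0.3, 0.05)
  c_at[4:6] <- c(0.10, 0.02, 0.01)
  c_at <- c_at / sum(c_at)
  rep1 <- find_active_solvent(c_at, seq_len(n), sys, threshold_factor = 1)
  expect_equal(rep1$c_min, c_at[3])
  expect_true(all(sys$reactive_atoms %in% rep1$involved_atoms))
  expect_true(3L %in% rep1$active_solvent_molecules)
  expect_identical(rep1$relevant_atoms,
                   sort(union(rep1$involved_atoms, sys$active_atoms)))

  # an atom at 0.9 c_min is admitted at factor 0.85, rejected at 1.0
  c_at2 <- c_at
  c_at2[7] <- 0.9 * rep1$c_min
  c_at2 <- c_at2 / sum(c_at2)
  r085 <- find_active_solvent(c_at2, seq_len(n), sys, 0.85)
  r100 <- find_active_solvent(c_at2, seq_len(n), sys, 1.0)
  expect_true(7L %in% r085$involved_atoms)
  expect_false(7L %in% r100$involved_atoms)

  # no solvent amplitude above threshold: n_active = 0
  c_none <- c(0.4, 0.35, 0.25, rep(1e-9, n - 3))
  c_none <- c_none / sum(c_none)
  expect_identical(find_active_solvent(c_none, seq_len(n), sys, 1)$n_active,
                   0L)
})

test_that("eigendecomposition satisfies residual and orthonormality bounds", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    sys <- all_solute_system(random_atom_cloud(n, seed = 20 + i))
    f <- runif(n); f <- f / sum(f)
    hd <- make_ts_hessian(synthetic_ts_spec(sys, f, seed = i))$hessian
    ms <- mode_set(hd)
    res <- hd$matrix %*% ms$vectors - ms$vectors %*% diag(ms$values)
    expect_lt(max(abs(res)), 1e-6 * max(abs(hd$matrix)))
    expect_lt(max(abs(crossprod(ms$vectors) - diag(3 * n))), 1e-10)
  }
})

test_that("Hessian files round-trip and asymmetry is rejected", {
  sys <- all_solute_system(random_atom_cloud(3, seed = 2))
  hd <- make_ts_hessian(synthetic_ts_spec(sys, c(0.5, 0.3, 0.2)))$hessian
  path <- withr::local_tempfile(fileext = ".hess")
  write_hessian(hd, path)
  back <- read_hessian(path)
  expect_lt(max(abs(back$matrix - hd$matrix)), 1e-10)
  A <- diag(6); A[1, 2] <- 0.5
  expect_error(hessian_data(A, 1:2), "not symmetric")
  expect_error(hessian_data(diag(5), 1:2), "dimension")
})
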