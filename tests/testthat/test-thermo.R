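# RRHO thermochemistry: closed-form component values, scaling laws,
# assembly identities, activation algebra and Eyring rates.

kB <- 1.380649e-23; hP <- 6.62607015e-34; Rg <- 8.314462618
cLight <- 299792458; amu_kg <- 1.66053906660e-27

test_that("translational terms match the Sackur-Tetrode evaluation", {
  cond <- thermo_conditions()
  tr <- translational(18.0153, cond)
  expect_equal(tr$U, 1.5 * Rg * 298.15 / 1000, tolerance = 1e-12)
  # independent Sackur-Tetrode evaluation (textbook water-vapor value)
  m <- 18.0153 * amu_kg
  S_oracle <- Rg * (2.5 + log((2 * pi * m * kB * 298.15 / hP^2)^1.5 *
                                kB * 298.15 / 101325))
  expect_equal(tr$S, S_oracle, tolerance = 1e-10)
  expect_equal(tr$S, 144.80, tolerance = 1e-4)
  # mass-scaling law: S(8m) - S(m) = (3/2) R ln 8
  expect_equal(translational(8 * 18.0153, cond)$S - tr$S,
               1.5 * Rg * log(8), tolerance = 1e-10)
})

test_that("rotational terms cover atoms, linear and asymmetric rotors", {
  cond <- thermo_conditions()
  expect_equal(rotational(c(0, 0, 0), cond), list(U = 0, S = 0))

  # linear rotor: two equal masses on an axis
  diat <- atomic_structure(c("N", "N"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  rl <- rotational(principal_moments(diat), cond)
  expect_equal(rl$U, Rg * 298.15 / 1000, tolerance = 1e-12)
  expect_gt(rl$S, 0)

  mom <- principal_moments(water_structure())
  rw <- rotational(mom, cond)
  # independent closed-form evaluation; sigma = 2 reproduces the textbook
  # water value ~43.7-43.9 J/(mol K)
  Isi <- mom * amu_kg * 1e-20
  S_oracle <- Rg * (1.5 + log(sqrt(pi) *
                                (8 * pi^2 * kB * 298.15 / hP^2)^1.5 *
                                sqrt(prod(Isi))))
  expect_equal(rw$S, S_oracle, tolerance = 1e-10)
  expect_equal(rotational(mom, thermo_conditions(sigma = 2))$S,
               rw$S - Rg * log(2), tolerance = 1e-10)
  expect_equal(rw$S - Rg * log(2), 43.72, tolerance = 1e-2)

  # doubling all moments raises S by (3/2) R ln 2
  expect_equal(rotational(2 * mom, cond)$S - rw$S, 1.5 * Rg * log(2),
               tolerance = 1e-10)
  expect_error(rotational(c(-1, 2, 3), cond), "negative moment")
})

test_that("vibrational terms match the harmonic closed form and its limits", {
  cond <- thermo_conditions()
  v <- vibrational(100, cond)
  x <- hP * 100 * 100 * cLight / (kB * 298.15)
  expect_equal(v$S, Rg * (x / expm1(x) - log1p(-exp(-x))), tolerance = 1e-10)
  expect_equal(v$S, 14.45, tolerance = 1e-2)

  # high-frequency limit: S -> 0, U -> ZPE
  hi <- vibrational(6000, cond)
  zpe <- 6.02214076e23 * hP * 6000 * 100 * cLight / 2 / 1000
  expect_lt(hi$S, 1e-9)
  expect_equal(hi$U, zpe, tolerance = 1e-9)

  expect_equal(vibrational(numeric(0), cond), list(U = 0, S = 0))
  expect_error(vibrational(c(100, -50), cond), "mode 2")

  # S_vib decreases with every frequency; U_vib increases with T
  expect_gt(vibrational(50, cond)$S, vibrational(60, cond)$S)
  expect_gt(vibrational(300, thermo_conditions(T = 400))$U,
            vibrational(300, thermo_conditions(T = 300))$U)
})

test_that("species assembly satisfies G = H - TS and the diatomic closed form", {
  cond <- thermo_conditions()
  # single atom: only translation and pV survive
  ar <- atomic_structure("Ar", matrix(0, 1, 3))
  th <- species_thermo(ar, E_el = -100, hessian = hessian_data(
    matrix(0, 3, 3), 1L), cond = cond)
  expect_equal(th$G, th$H - cond$T * th$S / 1000, tolerance = 1e-9)
  expect_equal(th$H, -100 + 2.5 * Rg * cond$T / 1000, tolerance = 1e-9)
  expect_equal(th$S, th$S_tra, tolerance = 1e-12)

  # analytic diatomic: nu = sqrt(k/mu)/(2 pi c), k in Hartree/Bohr^2
  kf <- 0.3
  u <- c(0, 0, 1)
  B <- kf * tcrossprod(u)
  H <- rbind(cbind(B, -B), cbind(-B, B))
  st <- atomic_structure(c("H", "Cl"), rbind(c(0, 0, 0), c(0, 0, 1.27)))
  th2 <- suppressWarnings(species_thermo(st, 0, hessian_data(H, 1:2), cond))
  mu_me <- prod(st$masses) / sum(st$masses) / 5.48579909065e-4
  nu_oracle <- sqrt(kf / mu_me) * 219474.6313632
  expect_length(th2$frequencies, 1)
  expect_equal(th2$frequencies, nu_oracle, tolerance = 0.1 / nu_oracle)
  expect_equal(th2$G, th2$H - cond$T * th2$S / 1000, tolerance = 1e-9)

  # a TS input must have exactly one imaginary mode, which is excluded
  Hneg <- rbind(cbind(-B, B), cbind(B, -B))
  th3 <- suppressWarnings(species_thermo(st, 0, hessian_data(Hneg, 1:2),
                                         cond, is_ts = TRUE))
  expect_identical(th3$imaginary_count, 1L)
  expect_length(th3$frequencies, 0)
  expect_error(suppressWarnings(
    species_thermo(st, 0, hessian_data(Hneg, 1:2), cond)), "imaginary")
})

test_that("activation quantities cancel translation and match brute force", {
  cond <- thermo_conditions()
  sys <- all_solute_system(random_atom_cloud(4, seed = 31))
  f <- c(0.4, 0.3, 0.2, 0.1)
  ts_h <- make_ts_hessian(synthetic_ts_spec(sys, f, seed = 3))$hessian
  # reactant: same structure, positive-definite Hessian built from the TS
  # one by flipping the negative eigenvalue
  e <- eigen(ts_h$matrix, symmetric = TRUE)
  Hr <- e$vectors %*% (abs(e$values) * t(e$vectors))
  st <- sys$structure
  th_r <- suppressWarnings(species_thermo(st, 10, hessian_data(Hr, 1:4),
                                          cond))
  th_ts <- suppressWarnings(species_thermo(st, 60, ts_h, cond,
                                           is_ts = TRUE))
  act <- activation(th_r, th_ts, cond)
  expect_equal(act$dE_el, 50)
  expect_equal(act$dH, act$dE_el + act$dU_vib, tolerance = 1e-12)
  expect_equal(act$dS, act$dS_rot + act$dS_vib, tolerance = 1e-12)
  expect_equal(act$dG, act$dH - cond$T * act$dS / 1000, tolerance = 1e-12)
  # brute-force difference of full G (translational terms included)
  expect_equal(act$dG, th_ts$G - th_r$G, tolerance = 1e-9)

  # identical species: all activation quantities vanish
  act0 <- activation(th_r, th_r, cond)
  expect_equal(act0$dG, 0, tolerance = 1e-12)
  expect_equal(act0$rate, kB * cond$T / hP, tolerance = 1e-9)

  other <- suppressWarnings(species_thermo(st, 10, hessian_data(Hr, 1:4),
                                           thermo_conditions(T = 300)))
  expect_error(activation(th_r, other, cond), "conditions")
})

test_that("Eyring rates reproduce the prefactor and known barriers", {
  expect_equal(eyring_rate(0, 298.15), kB * 298.15 / hP, tolerance = 1e-9)
  # a 67.1 kJ/mol barrier gives a rate of about 10.9 per second
  expect_equal(eyring_rate(67.1, 298.15), 10.91, tolerance = 1e-3)
  g <- seq(0, 100, by = 10)
  expect_true(all(diff(eyring_rate(g, 298.15)) < 0))
})
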