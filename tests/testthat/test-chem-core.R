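# Structure I/O, element tables, molecule partitioning, inertia moments
# and van-der-Waals hull volumes.

test_that("XYZ files round-trip and malformed inputs are rejected", {
  w <- water_structure()
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(w, path)
  back <- read_xyz(path)
  expect_identical(back$symbols, c("O", "H", "H"))
  expect_lt(max(abs(back$coordinates - w$coordinates)), 1e-6)

  # declared atom count larger than the number of atom lines
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "", "O 0 0 0", "H 1 0 0", "H 0 1 0", "H 0 0 1"), bad)
  expect_error(read_xyz(bad), "declares 5 atoms")

  # non-numeric coordinate names the offending line
  bad2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "O 0 zero 0"), bad2)
  expect_error(read_xyz(bad2), "line 3")

  # empty structure
  empty <- atomic_structure(character(0), matrix(numeric(0), 0, 3))
  p0 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(empty, p0)
  expect_identical(readLines(p0)[1], "0")

  # charge/multiplicity survive through the comment line
  ion <- atomic_structure("Cl", matrix(0, 1, 3), charge = -1L)
  p1 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(ion, p1)
  expect_identical(read_xyz(p1)$charge, -1L)
})

test_that("element tables resolve radii and masses", {
  expect_equal(unname(covalent_radius("H")), 0.31)
  expect_equal(unname(covalent_radius("O")), 0.66)
  expect_equal(unname(covalent_radius("Cl")), 1.02)
  expect_equal(unname(vdw_radius("C")), 1.70)
  expect_error(covalent_radius("Xq"), "unknown element")
})

test_that("molecule detection matches a brute-force bond scan", {
  # two waters 5 A apart -> two 3-atom molecules
  w <- water_structure()
  two <- atomic_structure(rep(w$symbols, 2),
                          rbind(w$coordinates,
                                sweep(w$coordinates, 2, c(5, 0, 0), `+`)))
  part <- detect_molecules(two)
  expect_length(part$molecules, 2)
  expect_identical(lengths(part$molecules), c(3L, 3L))

  # single atom is its own molecule
  expect_length(detect_molecules(atomic_structure("Ar", matrix(0, 1, 3)))$molecules, 1)

  # O-H at 0.96 A is bonded at tolerance 1.2 (0.96 <= 1.2 * 0.97)
  oh <- atomic_structure(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)))
  expect_length(detect_molecules(oh)$molecules, 1)

  # brute-force all-pairs oracle on random droplets (<= 50 atoms)
  for (seed in 1:5) {
    sys <- small_droplet(n_solvent = 6, seed = seed)
    st <- sys$structure
    part <- detect_molecules(st)
    n <- n_atoms(st)
    rc <- unname(covalent_radius(st$symbols))
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- sqrt(sum((st$coordinates[i, ] - st$coordinates[j, ])^2))
      adj[i, j] <- adj[j, i] <- d <= 1.2 * (rc[i] + rc[j])
    }
    # reachability by repeated multiplication (independent of igraph)
    reach <- adj | diag(n)
    for (k in seq_len(n)) reach <- (reach %*% reach) > 0
    comp_oracle <- unique(apply(reach, 1, function(r) which(r)[1]))
    expect_length(part$molecules, length(comp_oracle))
    # partition is a disjoint cover
    expect_setequal(unlist(part$molecules), seq_len(n))
  }
})

test_that("principal moments match textbook cases and obey the triangle rule", {
  expect_equal(principal_moments(atomic_structure("C", matrix(1, 1, 3))),
               c(0, 0, 0))
  diat <- atomic_structure(c("H", "H"), rbind(c(0, 0, 1), c(0, 0, -1)),
                           masses = c(1, 1))
  expect_equal(principal_moments(diat), c(0, 2, 2), tolerance = 1e-12)
  mom <- principal_moments(water_structure())
  expect_true(all(mom > 0) && all(diff(mom) > 1e-3))
  # Ic <= Ia + Ib for any mass distribution
  for (seed in 1:10) {
    mom <- principal_moments(random_atom_cloud(12, seed))
    expect_lte(mom[3], mom[1] + mom[2] + 1e-9)
  }
})

test_that("hull volumes respect the sphere bound and rigid-motion invariance", {
  carbon <- atomic_structure("C", matrix(0, 1, 3))
  v_sphere <- 4 / 3 * pi * 1.70^3
  v256 <- molecular_volume(carbon, 256)
  expect_lt(v256, v_sphere)
  expect_gt(v256, 0.95 * v_sphere)
  # inscribed-polyhedron volume increases toward the sphere volume
  expect_gt(molecular_volume(carbon, 1024), v256)

  st <- random_atom_cloud(8, seed = 3)
  v <- molecular_volume(st, 128)
  shifted <- st
  shifted$coordinates <- sweep(st$coordinates, 2, c(11.2, -3.4, 0.7), `+`)
  expect_equal(molecular_volume(shifted, 128), v, tolerance = 1e-9)
  rotated <- st
  rotated$coordinates <- st$coordinates %*% random_rotation(7)
  expect_equal(molecular_volume(rotated, 128), v, tolerance = 1e-6)

  # strictly larger hull when a second distant atom is added
  two <- atomic_structure(c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_gt(molecular_volume(two, 128), molecular_volume(carbon, 128))
})

test_that("convex hull volume is exact on polytopes with interior points", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(rbind(cube, c(0.5, 0.5, 0.5))), 1,
               tolerance = 1e-12)
  # regular tetrahedron with edge sqrt(2): volume 1/3
  tet <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  expect_equal(convex_hull_volume(rbind(tet, colMeans(tet))), 1 / 3,
               tolerance = 1e-12)
  expect_error(convex_hull_volume(cbind(1:9, 2 * (1:9), 3 * (1:9))),
               "collinear|degenerate")
})
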