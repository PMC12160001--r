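# Shared fixtures, all generated in code.

water_structure <- function() {
  atomic_structure(c("O", "H", "H"),
                   rbind(c(0, 0, 0.1173),
                         c(0, 0.7572, -0.4692),
                         c(0, -0.7572, -0.4692)))
}

# A random cloud of single atoms, far enough apart to stay unbonded.
random_atom_cloud <- function(n, seed, spread = 8) {
  set.seed(seed)
  atomic_structure(sample(c("C", "N", "O", "H"), n, replace = TRUE),
                   matrix(stats::runif(3 * n, -spread, spread), ncol = 3))
}

# A small seeded water droplet around the toy complex, as a full system.
small_droplet <- function(n_solvent = 5, seed = 1) {
  rx <- toy_reaction()
  make_droplet(rx$structure,
               droplet_config(n_solvent = n_solvent, seed = seed),
               reactive_atoms = rx$reactive_atoms,
               active_atoms = rx$active_atoms)
}

# Wrap a structure as a system whose molecules are all solute.
all_solute_system <- function(st, reactive_atoms = integer(0)) {
  part <- detect_molecules(st)
  molecular_system(st, molecule_partition(part$molecules,
                                          seq_along(part$molecules),
                                          n_atoms(st)),
                   reactive_atoms = reactive_atoms)
}

# Random rotation matrix (proper, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Brute-force sphere-region oracle: union of closed spheres, solute always
# included, whole-molecule closure. Independent of build_region.
brute_force_region <- function(system, centers, radii) {
  X <- system$structure$coordinates
  sel <- rep(FALSE, nrow(X))
  for (k in seq_along(centers)) {
    d <- sqrt(colSums((t(X) - X[centers[k], ])^2))
    sel <- sel | (d <= radii[k])
  }
  for (mid in system$partition$solute_ids)
    sel[system$partition$molecules[[mid]]] <- TRUE
  for (mid in system$partition$solvent_ids) {
    at <- system$partition$molecules[[mid]]
    if (any(sel[at])) sel[at] <- TRUE
  }
  which(sel)
}
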