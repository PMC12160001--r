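#' Molecule partition of a structure
#'
#' @param molecules List of integer vectors of atom indices; the sets must be
#'   disjoint and cover all atoms.
#' @param solute_ids Integer indices (into `molecules`) of the molecules
#'   forming the reactive complex.
#' @param n_atoms Total number of atoms covered.
#' @return An object of class `molecule_partition` with fields `molecules`,
#'   `solute_ids`, `solvent_ids`.
#' @export
molecule_partition <- function(molecules, solute_ids = integer(0),
                               n_atoms = sum(lengths(molecules))) {
  molecules <- lapply(molecules, function(m) sort(as.integer(m)))
  all_atoms <- unlist(molecules)
  if (anyDuplicated(all_atoms))
    stop("molecule sets must be disjoint", call. = FALSE)
  if (length(all_atoms) != n_atoms || !setequal(all_atoms, seq_len(n_atoms)))
    stop("molecule sets must cover atoms 1..n exactly", call. = FALSE)
  solute_ids <- sort(unique(as.integer(solute_ids)))
  if (length(solute_ids) && (min(solute_ids) < 1 ||
                             max(solute_ids) > length(molecules)))
    stop("solute_ids out of range", call. = FALSE)
  structure(list(molecules = molecules, solute_ids = solute_ids,
                 solvent_ids = setdiff(seq_along(molecules), solute_ids)),
            class = "molecule_partition")
}

#' Partition a structure into covalently bound molecules
#'
#' Atoms i and j are bonded when their distance does not exceed
#' `bond_tolerance * (r_cov_i + r_cov_j)`; the molecules are the connected
#' components of the resulting bond graph. Isolated atoms become single-atom
#' molecules.
#'
#' @param structure An [atomic_structure()].
#' @param bond_tolerance Dimensionless tolerance on covalent-radius sums
#'   (default 1.2).
#' @return A [molecule_partition()] with no solute assignment.
#' @export
detect_molecules <- function(structure, bond_tolerance = 1.2) {
  stopifnot(bond_tolerance > 0)
  n <- n_atoms(structure)
  if (n == 0) return(molecule_partition(list(), n_atoms = 0L))
  if (n == 1) return(molecule_partition(list(1L), n_atoms = 1L))
  rcov <- unname(covalent_radius(structure$symbols))
  d <- as.matrix(stats::dist(structure$coordinates))
  cut <- bond_tolerance * outer(rcov, rcov, `+`)
  adj <- d <= cut
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  mols <- split(seq_len(n), comp$membership)
  # order molecules by their lowest atom index for reproducibility
  mols <- mols[order(vapply(mols, min, 1L))]
  molecule_partition(unname(mols), n_atoms = n)
}

#' Molecular system: structure, partition and reactive/active atoms
#'
#' Bundles an [atomic_structure()] with its molecule partition and the two
#' designated atom sets: *reactive atoms* (assigned to form/break bonds in
#' the elementary step) and *active atoms* (solute atoms expected to
#' interact with solvent, e.g. hydrogen-bond donors/acceptors). Reactive
#' atoms must belong to solute molecules.
#'
#' @param structure An [atomic_structure()].
#' @param partition A [molecule_partition()]; computed with
#'   [detect_molecules()] if omitted. When computed, solute molecules can be
#'   supplied via `solute_molecules`.
#' @param reactive_atoms Integer atom indices.
#' @param active_atoms Integer atom indices.
#' @param solute_molecules Optional molecule indices marked as solute when
#'   `partition` is computed here.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(structure, partition = NULL,
                             reactive_atoms = integer(0),
                             active_atoms = integer(0),
                             solute_molecules = NULL) {
  stopifnot(inherits(structure, "atomic_structure"))
  if (is.null(partition)) {
    partition <- detect_molecules(structure)
    if (!is.null(solute_molecules))
      partition <- molecule_partition(partition$molecules,
                                      solute_ids = solute_molecules,
                                      n_atoms = n_atoms(structure))
  }
  stopifnot(inherits(partition, "molecule_partition"))
  n <- n_atoms(structure)
  reactive_atoms <- sort(unique(as.integer(reactive_atoms)))
  active_atoms <- sort(unique(as.integer(active_atoms)))
  ok <- function(v) !length(v) || (min(v) >= 1 && max(v) <= n)
  if (!ok(reactive_atoms) || !ok(active_atoms))
    stop("reactive/active atom indices out of range", call. = FALSE)
  solute_atoms <- solute_atoms_of(partition)
  if (!all(reactive_atoms %in% solute_atoms))
    stop("reactive atoms must belong to solute molecules", call. = FALSE)
  structure(list(structure = structure, partition = partition,
                 reactive_atoms = reactive_atoms, active_atoms = active_atoms),
            class = "molecular_system")
}

#' Atom indices of all solute molecules in a partition
#' @param partition A [molecule_partition()].
#' @return Sorted integer vector of atom indices.
#' @export
solute_atoms_of <- function(partition) {
  sort(unlist(partition$molecules[partition$solute_ids], use.names = FALSE))
}

#' Molecule index containing each atom
#' @param partition A [molecule_partition()].
#' @return Integer vector mapping atom index to molecule index.
#' @export
molecule_of_atom <- function(partition) {
  n <- sum(lengths(partition$molecules))
  out <- integer(n)
  for (k in seq_along(partition$molecules)) out[partition$molecules[[k]]] <- k
  out
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", n_atoms(x$structure), " atoms, ",
      length(x$partition$molecules), " molecules (",
      length(x$partition$solute_ids), " solute), ",
      length(x$reactive_atoms), " reactive / ",
      length(x$active_atoms), " active atoms\n", sep = "")
  invisible(x)
}
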