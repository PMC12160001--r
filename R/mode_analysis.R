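# Reaction-coordinate selection from the eigenvectors of a (partial)
# non-mass-weighted Hessian, and identification of the solvent molecules
# that actively participate in the decaying transition-state mode.

#' Eigenpairs of a Hessian
#'
#' Dense symmetric diagonalization; eigenvalues ascending, eigenvectors as
#' unit-norm columns (Cartesian displacements per atom).
#'
#' @param hessian A [hessian_data()].
#' @return An object of class `mode_set` with `values` (ascending) and
#'   `vectors`.
#' @export
mode_set <- function(hessian) {
  stopifnot(inherits(hessian, "hessian_data"))
  e <- eigen(hessian$matrix, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(values = e$values[ord],
                 vectors = e$vectors[, ord, drop = FALSE],
                 atom_ids = hessian$atom_ids),
            class = "mode_set")
}

#' Mass-weight and normalize a Cartesian mode vector
#'
#' Each atom's three Cartesian components are multiplied elementwise by that
#' atom's mass (raised to `mass_power`), damping the otherwise dominant
#' amplitudes of light atoms, and the result is renormalized to unit
#' Euclidean norm. The default `mass_power = 1` weights by m; set 0.5 for
#' the sqrt(m) convention of conventional normal-mode theory.
#'
#' @param n Numeric vector of length 3N (x1,y1,z1,x2,...).
#' @param masses Numeric vector of N atomic masses (amu).
#' @param mass_power Exponent applied to the masses (default 1).
#' @return Unit-norm numeric vector of length 3N.
#' @export
mass_weight_and_normalize <- function(n, masses, mass_power = 1) {
  if (length(n) != 3L * length(masses))
    stop("mode length must be 3 x number of masses", call. = FALSE)
  if (sqrt(sum(n^2)) == 0) stop("zero mode vector", call. = FALSE)
  w <- rep(masses^mass_power, each = 3L)
  nm <- n * w
  nm / sqrt(sum(nm^2))
}

#' Total reactive-atom contribution of a mode
#'
#' Sum of the squared Cartesian components of the mass-weighted, normalized
#' mode over the reactive atoms; lies in \[0, 1\].
#'
#' @param n_norm_m Unit-norm mass-weighted mode vector (length 3N).
#' @param reactive_atoms Indices (1..N, local to the mode's atom list) of
#'   the reactive atoms.
#' @return Scalar contribution C in \[0, 1\].
#' @export
reactive_contribution <- function(n_norm_m, reactive_atoms) {
  if (!length(reactive_atoms))
    stop("reactive atom set is empty; contribution undefined", call. = FALSE)
  idx <- as.vector(outer(-2:0, 3L * as.integer(reactive_atoms), `+`))
  sum(n_norm_m[idx]^2)
}

#' Score the negative-eigenvalue modes and select the reaction coordinate
#'
#' Every mode with a negative eigenvalue w is scored as
#' `s = w_weight * w/w_min + C_weight * C`, where `w_min` is the most
#' negative eigenvalue (so `w/w_min` lies in \[0,1\]) and C is the
#' reactive-atom contribution of the mass-weighted mode. The mode with the
#' highest score is selected; ties go to the more negative eigenvalue.
#'
#' @param modes A [mode_set()].
#' @param masses Masses (amu) of the atoms the modes span.
#' @param reactive_atoms Local (1..N) indices of reactive atoms.
#' @param weights Length-2 numeric `c(w_weight, C_weight)` (default
#'   `c(0.5, 0.5)`).
#' @param mass_power Passed to [mass_weight_and_normalize()].
#' @return A `mode_score_table`: data.frame with columns `mode`, `w`,
#'   `w_norm`, `C`, `score`, plus attribute `selected` (row index of the
#'   selected mode) and `selected_mode` (column index into `modes$vectors`).
#' @export
score_modes <- function(modes, masses, reactive_atoms,
                        weights = c(0.5, 0.5), mass_power = 1) {
  stopifnot(inherits(modes, "mode_set"), length(weights) == 2)
  neg <- which(modes$values < 0)
  if (!length(neg))
    stop("no negative eigenvalue: structure has no transition-state ",
         "character", call. = FALSE)
  w <- modes$values[neg]
  w_min <- min(w)
  w_norm <- w / w_min
  C <- vapply(neg, function(k) {
    nm <- mass_weight_and_normalize(modes$vectors[, k], masses, mass_power)
    reactive_contribution(nm, reactive_atoms)
  }, 1.0)
  score <- weights[1] * w_norm + weights[2] * C
  best <- score >= max(score) - 1e-12
  sel <- which(best)[which.min(w[best])]
  tab <- data.frame(mode = neg, w = w, w_norm = w_norm, C = C, score = score)
  attr(tab, "selected") <- sel
  attr(tab, "selected_mode") <- neg[sel]
  class(tab) <- c("mode_score_table", "data.frame")
  tab
}

#' Per-atom contributions of a selected mode
#'
#' Squared per-atom norm of the mass-weighted, normalized mode; the
#' contributions sum to 1.
#'
#' @param selected Cartesian mode vector (length 3N, need not be
#'   pre-weighted).
#' @param masses Masses (amu) of the N atoms.
#' @inheritParams mass_weight_and_normalize
#' @return Numeric vector of N contributions summing to 1.
#' @export
atom_contributions <- function(selected, masses, mass_power = 1) {
  nm <- mass_weight_and_normalize(selected, masses, mass_power)
  colSums(matrix(nm^2, nrow = 3L))
}

#' Identify involved atoms and active solvent molecules
#'
#' The threshold is the minimum contribution over the reactive atoms,
#' `c_min`. Atoms with `c_i >= threshold_factor * c_min` form the
#' *involved atoms*; solvent molecules containing at least one involved
#' atom are the *active solvent molecules*; involved atoms plus the
#' system's active atoms form the *relevant atoms* used as sphere centers
#' for the next-stage region.
#'
#' @param c_atoms Per-atom contributions (local to `atom_ids`).
#' @param atom_ids Global atom indices the contributions refer to.
#' @param system A [molecular_system()].
#' @param threshold_factor Dimensionless factor on `c_min` (default 1;
#'   0.85 is the looser grouping variant used in ensemble analyses).
#' @return An object of class `contribution_report` with fields `c`
#'   (named by global atom id), `c_min`, `threshold_factor`,
#'   `involved_atoms`, `relevant_atoms` (global ids),
#'   `active_solvent_molecules` (molecule ids) and `n_active`.
#' @export
find_active_solvent <- function(c_atoms, atom_ids, system,
                                threshold_factor = 1) {
  stopifnot(threshold_factor > 0, length(c_atoms) == length(atom_ids))
  reactive <- system$reactive_atoms
  if (!length(reactive)) stop("reactive atom set is empty", call. = FALSE)
  loc <- match(reactive, atom_ids)
  if (anyNA(loc))
    stop("reactive atoms missing from the Hessian's atom set", call. = FALSE)
  c_min <- min(c_atoms[loc])
  involved <- atom_ids[c_atoms >= threshold_factor * c_min]
  mol_of <- molecule_of_atom(system$partition)
  active_mols <- sort(intersect(unique(mol_of[involved]),
                                system$partition$solvent_ids))
  relevant <- sort(union(involved, system$active_atoms))
  structure(list(c = stats::setNames(c_atoms, atom_ids), c_min = c_min,
                 threshold_factor = threshold_factor,
                 involved_atoms = sort(involved), relevant_atoms = relevant,
                 active_solvent_molecules = active_mols,
                 n_active = length(active_mols)),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat("<contribution_report> c_min=", signif(x$c_min, 4),
      " (factor ", x$threshold_factor, "), ",
      length(x$involved_atoms), " involved atoms, ",
      x$n_active, " active solvent molecule(s)\n", sep = "")
  invisible(x)
}

#' Full mode analysis of a (partial) transition-state Hessian
#'
#' Convenience wrapper: diagonalizes the Hessian, scores the
#' negative-eigenvalue modes, selects the reaction-coordinate mode, computes
#' per-atom contributions and identifies the active solvent molecules.
#'
#' @param hessian A [hessian_data()] spanning a subset of the system atoms
#'   that contains all reactive atoms.
#' @param system A [molecular_system()].
#' @inheritParams find_active_solvent
#' @inheritParams score_modes
#' @return A list with `scores` (mode_score_table), `selected_mode`
#'   (eigenvector index), `report` (contribution_report).
#' @export
analyze_modes <- function(hessian, system, threshold_factor = 1,
                          weights = c(0.5, 0.5), mass_power = 1) {
  modes <- mode_set(hessian)
  masses <- system$structure$masses[hessian$atom_ids]
  reactive_local <- match(system$reactive_atoms, hessian$atom_ids)
  if (anyNA(reactive_local))
    stop("reactive atoms must be spanned by the Hessian", call. = FALSE)
  scores <- score_modes(modes, masses, reactive_local, weights, mass_power)
  k <- attr(scores, "selected_mode")
  c_atoms <- atom_contributions(modes$vectors[, k], masses, mass_power)
  report <- find_active_solvent(c_atoms, hessian$atom_ids, system,
                                threshold_factor)
  list(scores = scores, selected_mode = k, modes = modes, report = report)
}
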