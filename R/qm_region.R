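# Sphere-based QM-region construction with whole-solvent-molecule
# inclusion, for the staged large/medium/small (lQM/mQM/sQM) regions.

#' Sphere-radius policy for QM-region construction
#'
#' Two modes: `"fixed"` uses one radius `r_c` for every center;
#' `"scaled"` uses a type-dependent radius `s * (r_cov(center) +
#' r_cov(probe_element))`, which follows hydrogen-bonded solvent molecules
#' more naturally in protic solvents. The probe element's covalent radius
#' plays the solvent-side role and can be swapped for a solvent-specific
#' element (e.g. Cl for dichloromethane).
#'
#' @param mode `"fixed"` or `"scaled"`.
#' @param r_c Fixed radius in Angstrom (default 4.5).
#' @param s Dimensionless scaling factor (default 2.3).
#' @param probe_element Element whose covalent radius is added to the
#'   center's (default `"H"`).
#' @return An object of class `radius_policy`.
#' @export
radius_policy <- function(mode = c("fixed", "scaled"), r_c = 4.5, s = 2.3,
                          probe_element = "H") {
  mode <- match.arg(mode)
  stopifnot(r_c > 0, s >= 0)
  structure(list(mode = mode, r_c = r_c, s = s,
                 probe_element = probe_element),
            class = "radius_policy")
}

#' Sphere radius around a center atom under a policy
#'
#' @param center_symbol Element symbol of the center atom.
#' @param policy A [radius_policy()].
#' @return Radius in Angstrom.
#' @export
sphere_radius <- function(center_symbol, policy) {
  stopifnot(inherits(policy, "radius_policy"))
  if (policy$mode == "fixed") return(rep(policy$r_c, length(center_symbol)))
  unname(policy$s * (covalent_radius(center_symbol) +
                       covalent_radius(policy$probe_element)[1]))
}

#' Atoms within a sphere around a center atom
#'
#' Closed inequality: an atom exactly at distance `r_s` is included, and the
#' center is always a member.
#'
#' @param system A [molecular_system()].
#' @param center Atom index of the sphere center.
#' @param r_s Sphere radius in Angstrom (>= 0).
#' @return Sorted integer vector of atom indices.
#' @export
atoms_within <- function(system, center, r_s) {
  stopifnot(inherits(system, "molecular_system"), r_s >= 0)
  coords <- system$structure$coordinates
  n <- nrow(coords)
  if (center < 1 || center > n) stop("invalid center index", call. = FALSE)
  d <- sqrt(rowSums(sweep(coords, 2, coords[center, ])^2))
  which(d <= r_s)
}

#' Build a QM region from sphere centers
#'
#' Takes the union of the spheres around all centers, then (a) adds every
#' atom of the reactive complex unconditionally and (b) includes every
#' solvent molecule with at least one atom inside the union in full (no
#' solvent molecule is ever split).
#'
#' @param system A [molecular_system()].
#' @param centers Non-empty integer vector of center atom indices.
#' @param policy A [radius_policy()].
#' @return An object of class `region_selection` with fields `atom_ids`
#'   (sorted), `center_atoms`, `per_center_radii` and `policy`.
#' @export
build_region <- function(system, centers, policy) {
  centers <- sort(unique(as.integer(centers)))
  if (!length(centers)) stop("centers must be nonempty", call. = FALSE)
  n <- n_atoms(system$structure)
  if (min(centers) < 1 || max(centers) > n)
    stop("center index out of range", call. = FALSE)
  radii <- sphere_radius(system$structure$symbols[centers], policy)
  sel <- logical(n)
  for (k in seq_along(centers))
    sel[atoms_within(system, centers[k], radii[k])] <- TRUE
  sel[solute_atoms_of(system$partition)] <- TRUE
  part <- system$partition
  for (mid in part$solvent_ids) {
    atoms <- part$molecules[[mid]]
    if (any(sel[atoms])) sel[atoms] <- TRUE
  }
  structure(list(atom_ids = which(sel), center_atoms = centers,
                 per_center_radii = radii, policy = policy),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat("<region_selection> ", length(x$atom_ids), " atoms, ",
      length(x$center_atoms), " centers, policy ", x$policy$mode,
      if (x$policy$mode == "fixed") sprintf(" (r_c=%.2f A)", x$policy$r_c)
      else sprintf(" (s=%.2f)", x$policy$s), "\n", sep = "")
  invisible(x)
}

#' Stage-default QM region
#'
#' Applies the per-stage default policy: `lQM` uses a fixed 4.5 Angstrom
#' radius around the union of reactive and active atoms; `mQM` uses scaled
#' type-dependent radii with s = 2.3 around the supplied relevant atoms;
#' `sQM` the same with s = 2.0.
#'
#' @param system A [molecular_system()].
#' @param stage One of `"lQM"`, `"mQM"`, `"sQM"`.
#' @param relevant_atoms Centers for the mQM/sQM stages (the relevant-atom
#'   set from the mode analysis). Ignored for `lQM`.
#' @param policy Optional [radius_policy()] overriding the stage default.
#' @return A `region_selection`.
#' @export
stage_region <- function(system, stage, relevant_atoms = NULL, policy = NULL) {
  if (!stage %in% c("lQM", "mQM", "sQM"))
    stop("unknown stage: ", stage, call. = FALSE)
  if (stage == "lQM") {
    centers <- union(system$reactive_atoms, system$active_atoms)
    if (is.null(policy)) policy <- radius_policy("fixed", r_c = 4.5)
  } else {
    centers <- relevant_atoms
    if (is.null(centers) || !length(centers))
      stop("relevant_atoms must be nonempty for ", stage, call. = FALSE)
    if (is.null(policy))
      policy <- radius_policy("scaled", s = if (stage == "mQM") 2.3 else 2.0)
  }
  if (!length(centers)) stop("no centers for stage ", stage, call. = FALSE)
  build_region(system, centers, policy)
}
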