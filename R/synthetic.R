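# Seeded generators: solvent microdroplets around a reactive complex and
# synthetic transition-state Hessians whose decaying mode has prescribed
# per-atom participation (ground truth for recovery tests).

# Run code with a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Microdroplet configuration
#'
#' Two spherical shells of solvent molecules are placed around the reactive
#' complex. Shell radii default to the complex extent plus
#' `[2.5, 5.5]` and `[5.5, 8.5]` Angstrom, a sizing that yields roughly one
#' hundred waters for small solutes at the default `n_solvent`.
#'
#' @param n_solvent Total number of solvent molecules (default 100, split
#'   evenly between the shells).
#' @param shell_radii Optional 2 x 2 matrix `rbind(c(in1, out1), c(in2,
#'   out2))` of shell radii in Angstrom; computed from the complex extent
#'   when `NULL`.
#' @param min_separation Minimum allowed distance between atoms of
#'   different molecules, in Angstrom (default 1.8).
#' @param seed Integer RNG seed.
#' @param solvent A [solvent_spec()] with a template geometry (default
#'   packaged water).
#' @param max_attempts Placement attempts per molecule before giving up.
#' @return An object of class `droplet_config`.
#' @export
droplet_config <- function(n_solvent = 100, shell_radii = NULL,
                           min_separation = 1.8, seed = 1,
                           solvent = load_solvent("water"),
                           max_attempts = 500) {
  stopifnot(n_solvent >= 0, min_separation > 0, max_attempts >= 1)
  if (!is.null(shell_radii)) {
    shell_radii <- matrix(shell_radii, ncol = 2)
    if (any(shell_radii[, 1] >= shell_radii[, 2]))
      stop("each shell needs inner < outer radius", call. = FALSE)
  }
  structure(list(n_solvent = as.integer(n_solvent),
                 shell_radii = shell_radii,
                 min_separation = min_separation, seed = as.integer(seed),
                 solvent = solvent, max_attempts = as.integer(max_attempts)),
            class = "droplet_config")
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Assemble a seeded solvent microdroplet around a reactive complex
#'
#' Centers the complex at the origin and places solvent template copies
#' with uniformly random positions (volume-uniform within each shell) and
#' orientations (unit quaternions), rejecting placements that bring any
#' atom closer than `min_separation` to an already placed atom. The result
#' is a pure function of the inputs and the seed.
#'
#' @param rc [atomic_structure()] of the reactive complex.
#' @param config A [droplet_config()].
#' @param reactive_atoms,active_atoms Atom indices (into `rc`) carried into
#'   the returned system.
#' @return A [molecular_system()] whose solute molecules are those of the
#'   complex.
#' @export
make_droplet <- function(rc, config = droplet_config(),
                         reactive_atoms = integer(0),
                         active_atoms = integer(0)) {
  stopifnot(inherits(rc, "atomic_structure"),
            inherits(config, "droplet_config"))
  rc_coords <- sweep(rc$coordinates, 2, colMeans(rc$coordinates))
  r_max <- if (n_atoms(rc)) max(sqrt(rowSums(rc_coords^2))) else 0
  shells <- config$shell_radii
  if (is.null(shells))
    shells <- rbind(c(r_max + 2.5, r_max + 5.5), c(r_max + 5.5, r_max + 8.5))
  tpl <- config$solvent$template_geometry
  if (is.null(tpl)) stop("solvent has no template geometry", call. = FALSE)
  tpl_coords <- sweep(tpl$coordinates, 2, colMeans(tpl$coordinates))
  n1 <- ceiling(config$n_solvent / 2)
  shell_of <- rep(1:2, c(n1, config$n_solvent - n1))

  placed <- .with_seed(config$seed, {
    all_coords <- rc_coords
    mols <- list()
    for (k in seq_len(config$n_solvent)) {
      sh <- shells[shell_of[k], ]
      ok <- FALSE
      for (att in seq_len(config$max_attempts)) {
        r <- (stats::runif(1, sh[1]^3, sh[2]^3))^(1 / 3)
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pos <- r * u
        cand <- tpl_coords %*% t(.random_rotation())
        cand <- sweep(cand, 2, pos, `+`)
        d2 <- outer(rowSums(cand^2), rowSums(all_coords^2), `+`) -
          2 * cand %*% t(all_coords)
        dmin <- sqrt(max(0, min(d2)))
        if (dmin >= config$min_separation) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place solvent molecule ", k, " after ",
             config$max_attempts, " attempts; enlarge the shells or ",
             "reduce n_solvent", call. = FALSE)
      mols[[k]] <- cand
      all_coords <- rbind(all_coords, cand)
    }
    mols
  })

  symbols <- c(rc$symbols, rep(tpl$symbols, config$n_solvent))
  coords <- do.call(rbind, c(list(rc_coords), placed))
  full <- atomic_structure(symbols, coords, charge = rc$charge,
                           multiplicity = rc$multiplicity,
                           comment = "seeded microdroplet")
  rc_part <- detect_molecules(rc)
  n_rc_mol <- length(rc_part$molecules)
  mols <- rc_part$molecules
  ofs <- n_atoms(rc)
  nt <- n_atoms(tpl)
  for (k in seq_len(config$n_solvent)) {
    mols[[n_rc_mol + k]] <- ofs + seq_len(nt)
    ofs <- ofs + nt
  }
  part <- molecule_partition(mols, solute_ids = seq_len(n_rc_mol),
                             n_atoms = n_atoms(full))
  molecular_system(full, part, reactive_atoms = reactive_atoms,
                   active_atoms = active_atoms)
}

#' Synthetic transition-state Hessian specification
#'
#' @param system A [molecular_system()]; the Hessian spans all its atoms.
#' @param target_fractions Numeric vector of per-atom contributions of the
#'   decaying mode (length = number of atoms, summing to 1).
#' @param negative_eigenvalue The single prescribed negative eigenvalue
#'   (Hartree/Bohr^2, default -0.05).
#' @param positive_range Range for the remaining (positive) eigenvalues.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_ts_spec`.
#' @export
synthetic_ts_spec <- function(system, target_fractions,
                              negative_eigenvalue = -0.05,
                              positive_range = c(0.02, 0.8), seed = 1) {
  stopifnot(inherits(system, "molecular_system"),
            negative_eigenvalue < 0, all(positive_range > 0))
  n <- n_atoms(system$structure)
  if (length(target_fractions) != n)
    stop("need one fraction per atom", call. = FALSE)
  if (abs(sum(target_fractions) - 1) > 1e-9)
    stop("target fractions must sum to 1", call. = FALSE)
  if (any(target_fractions < 0)) stop("fractions must be >= 0", call. = FALSE)
  structure(list(system = system, target_fractions = target_fractions,
                 negative_eigenvalue = negative_eigenvalue,
                 positive_range = sort(positive_range),
                 seed = as.integer(seed)),
            class = "synthetic_ts_spec")
}

#' Build a synthetic TS Hessian with prescribed mode participation
#'
#' Constructs a Cartesian unit vector whose mass-weighted squared per-atom
#' norms equal the prescribed fractions (per-atom amplitude proportional
#' to sqrt(fraction)/mass), completes it to a seeded orthonormal basis and
#' assembles `H = V diag(lambda) V^T` with exactly one negative
#' eigenvalue. The analytically known contribution report is returned as
#' ground truth.
#'
#' @param spec A [synthetic_ts_spec()].
#' @param threshold_factor Passed to [find_active_solvent()] for the
#'   ground-truth report.
#' @return List with `hessian` ([hessian_data()]), `mode` (the prescribed
#'   unit eigenvector) and `truth` (a `contribution_report`, or `NULL`
#'   when the system designates no reactive atoms).
#' @export
make_ts_hessian <- function(spec, threshold_factor = 1) {
  stopifnot(inherits(spec, "synthetic_ts_spec"))
  sys <- spec$system
  n <- n_atoms(sys$structure)
  f <- spec$target_fractions
  m <- sys$structure$masses
  out <- .with_seed(spec$seed, {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    amp <- sqrt(f) / m
    v <- as.vector(t(u * amp))
    v <- v / sqrt(sum(v^2))
    M <- cbind(v, matrix(stats::rnorm(3 * n * (3 * n - 1)), 3 * n))
    V <- qr.Q(qr(M))
    lam <- c(spec$negative_eigenvalue,
             sort(stats::runif(3 * n - 1, spec$positive_range[1],
                               spec$positive_range[2])))
    H <- V %*% (lam * t(V))
    list(H = (H + t(H)) / 2, v = v)
  })
  truth <- if (length(sys$reactive_atoms))
    find_active_solvent(f, seq_len(n), sys, threshold_factor) else NULL
  list(hessian = hessian_data(out$H, seq_len(n)), mode = out$v,
       truth = truth)
}
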