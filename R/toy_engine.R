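# Analytic toy potential: harmonic bonds, one double-well interatomic
# coordinate (guaranteeing a first-order saddle at a known location),
# pairwise intermolecular repulsion and an optional flat-bottom droplet
# confinement. All terms depend on interatomic (or atom-origin) distances
# only, so energy, gradient and Hessian are available in closed form.
# Internal units: Hartree and Angstrom; exported Hessians are converted to
# Hartree/Bohr^2.

.TERM_HARM <- 1L; .TERM_DWELL <- 2L; .TERM_REP <- 3L; .TERM_CONF <- 4L

# f(d), f'(d), f''(d) for each term type (vectorized over terms)
.term_eval <- function(type, p1, p2, p3, d, order = 0L) {
  f <- fp <- fpp <- numeric(length(d))
  h <- type == .TERM_HARM
  if (any(h)) {
    dd <- d[h] - p2[h]
    f[h] <- 0.5 * p1[h] * dd^2
    if (order > 0) fp[h] <- p1[h] * dd
    if (order > 1) fpp[h] <- p1[h]
  }
  w <- type == .TERM_DWELL
  if (any(w)) {
    dd <- d[w] - p2[w]; w4 <- p3[w]^4
    f[w] <- p1[w] * (dd^2 - p3[w]^2)^2 / w4
    if (order > 0) fp[w] <- 4 * p1[w] * dd * (dd^2 - p3[w]^2) / w4
    if (order > 1) fpp[w] <- 4 * p1[w] * (3 * dd^2 - p3[w]^2) / w4
  }
  r <- type == .TERM_REP
  if (any(r)) {
    f[r] <- p1[r] / d[r]^6
    if (order > 0) fp[r] <- -6 * p1[r] / d[r]^7
    if (order > 1) fpp[r] <- 42 * p1[r] / d[r]^8
  }
  cf <- type == .TERM_CONF
  if (any(cf)) {
    dd <- pmax(0, d[cf] - p2[cf])
    f[cf] <- 0.5 * p1[cf] * dd^2
    if (order > 0) fp[cf] <- p1[cf] * dd
    if (order > 1) fpp[cf] <- p1[cf] * (dd > 0)
  }
  list(f = f, fp = fp, fpp = fpp)
}

#' Analytic toy potential engine
#'
#' Builds an engine over a [molecular_system()]: explicit harmonic bonds
#' and one optional double-well term for the reactive complex, automatic
#' harmonic bonds rigidifying each solvent molecule (every intramolecular
#' pair closer than `solvent_bond_cut`, with its current distance as rest
#' length), `A/d^6` repulsion between all atoms of different molecules,
#' and an optional flat-bottom spherical confinement that keeps the
#' droplet together.
#'
#' The engine object exposes `energy(coords)` (Hartree),
#' `gradient(coords)` (Hartree/Angstrom, N x 3), `hessian(coords,
#' atom_ids)` (a [hessian_data()] in Hartree/Bohr^2; a subset of atoms
#' yields a partial Hessian with the rest frozen), `with_bond(i, j, k,
#' r0)` (a new engine with one extra restraint) and `subset(atom_ids)`
#' (an engine for the isolated subsystem).
#'
#' @param system A [molecular_system()].
#' @param bonds Data frame with columns `i, j, k, r0` of explicit harmonic
#'   bonds (typically the reactive complex's).
#' @param dwell Optional `list(i, j, h, c, w)`: double-well
#'   `h ((d-c)^2 - w^2)^2 / w^4` on the distance of atoms i,j — minima at
#'   `c - w` and `c + w`, barrier `h` at `d = c`.
#' @param repulsion_A Repulsion prefactor in Hartree Angstrom^6 (0 turns
#'   it off).
#' @param confinement Optional `list(k, R)`: flat-bottom radial wall.
#' @param solvent_bond_k Force constant for auto-generated solvent bonds.
#' @param solvent_bond_cut Distance cutoff for auto-generated solvent
#'   bonds.
#' @return An object of class `toy_engine`.
#' @export
toy_engine <- function(system, bonds = NULL, dwell = NULL,
                       repulsion_A = 0.002, confinement = NULL,
                       solvent_bond_k = 0.6, solvent_bond_cut = 2.0) {
  stopifnot(inherits(system, "molecular_system"))
  n <- n_atoms(system$structure)
  part <- system$partition
  ti <- integer(0); tj <- integer(0); type <- integer(0)
  p1 <- numeric(0); p2 <- numeric(0); p3 <- numeric(0)
  add <- function(i, j, ty, a, b = 0, c = 0) {
    ti <<- c(ti, as.integer(i)); tj <<- c(tj, as.integer(j))
    type <<- c(type, ty); p1 <<- c(p1, a); p2 <<- c(p2, b); p3 <<- c(p3, c)
  }
  if (!is.null(bonds) && nrow(bonds))
    for (r in seq_len(nrow(bonds)))
      add(bonds$i[r], bonds$j[r], .TERM_HARM, bonds$k[r], bonds$r0[r])
  if (!is.null(dwell))
    add(dwell$i, dwell$j, .TERM_DWELL, dwell$h, dwell$c, dwell$w)
  # rigidify solvent molecules at their current internal geometry
  X <- system$structure$coordinates
  for (mid in part$solvent_ids) {
    at <- part$molecules[[mid]]
    if (length(at) < 2) next
    for (a in seq_along(at)) for (b in seq_len(a - 1L)) {
      d0 <- sqrt(sum((X[at[a], ] - X[at[b], ])^2))
      if (d0 <= solvent_bond_cut)
        add(at[a], at[b], .TERM_HARM, solvent_bond_k, d0)
    }
  }
  if (repulsion_A > 0 && length(part$molecules) > 1) {
    mol_of <- molecule_of_atom(part)
    pr <- utils::combn(n, 2)
    inter <- mol_of[pr[1, ]] != mol_of[pr[2, ]]
    for (kk in which(inter)) add(pr[1, kk], pr[2, kk], .TERM_REP, repulsion_A)
  }
  if (!is.null(confinement))
    for (i in seq_len(n)) add(i, n + 1L, .TERM_CONF, confinement$k,
                              confinement$R)

  terms <- list(ti = ti, tj = tj, type = type, p1 = p1, p2 = p2, p3 = p3)
  .toy_engine_from_terms(system, terms, dwell)
}

.toy_engine_from_terms <- function(system, terms, dwell) {
  n <- n_atoms(system$structure)
  k <- solv_constants

  dists <- function(X) {
    X0 <- rbind(X, c(0, 0, 0))
    dx <- X0[terms$ti, , drop = FALSE] - X0[terms$tj, , drop = FALSE]
    list(dx = dx, d = sqrt(rowSums(dx^2)))
  }
  # `restraint` is an optional list(i, j, k, r0) harmonic added on the fly
  # (used for coordinate driving) without rebuilding the engine.
  energy <- function(coords, restraint = NULL) {
    e <- 0
    if (length(terms$ti)) {
      d <- dists(coords)$d
      e <- sum(.term_eval(terms$type, terms$p1, terms$p2, terms$p3, d, 0L)$f)
    }
    if (!is.null(restraint)) {
      dr <- sqrt(sum((coords[restraint$i, ] - coords[restraint$j, ])^2))
      e <- e + 0.5 * restraint$k * (dr - restraint$r0)^2
    }
    e
  }
  gradient <- function(coords, restraint = NULL) {
    G <- matrix(0, n + 1L, 3)
    if (length(terms$ti)) {
      dd <- dists(coords)
      ev <- .term_eval(terms$type, terms$p1, terms$p2, terms$p3, dd$d, 1L)
      gv <- ifelse(dd$d > 1e-12, ev$fp / dd$d, 0)
      contrib <- dd$dx * gv
      ai <- rowsum(contrib, terms$ti)
      G[as.integer(rownames(ai)), ] <- G[as.integer(rownames(ai)), ] + ai
      aj <- rowsum(contrib, terms$tj)
      G[as.integer(rownames(aj)), ] <- G[as.integer(rownames(aj)), ] - aj
    }
    if (!is.null(restraint)) {
      dx <- coords[restraint$i, ] - coords[restraint$j, ]
      dr <- sqrt(sum(dx^2))
      if (dr > 1e-12) {
        gg <- restraint$k * (dr - restraint$r0) * dx / dr
        G[restraint$i, ] <- G[restraint$i, ] + gg
        G[restraint$j, ] <- G[restraint$j, ] - gg
      }
    }
    G[seq_len(n), , drop = FALSE]
  }
  hessian_full <- function(coords) {
    H <- matrix(0, 3L * n, 3L * n)
    if (!length(terms$ti)) return(H)
    dd <- dists(coords)
    ev <- .term_eval(terms$type, terms$p1, terms$p2, terms$p3, dd$d, 2L)
    for (t in seq_along(terms$ti)) {
      d <- dd$d[t]
      if (d < 1e-12) next
      u <- dd$dx[t, ] / d
      uu <- tcrossprod(u)
      B <- ev$fpp[t] * uu + (ev$fp[t] / d) * (diag(3) - uu)
      i <- terms$ti[t]; j <- terms$tj[t]
      ii <- 3L * (i - 1L) + 1:3
      H[ii, ii] <- H[ii, ii] + B
      if (j <= n) {
        jj <- 3L * (j - 1L) + 1:3
        H[jj, jj] <- H[jj, jj] + B
        H[ii, jj] <- H[ii, jj] - B
        H[jj, ii] <- H[jj, ii] - B
      }
    }
    H
  }
  hessian <- function(coords, atom_ids = NULL) {
    H <- hessian_full(coords) * k$bohr^2  # Hartree/A^2 -> Hartree/Bohr^2
    if (is.null(atom_ids))
      return(hessian_data(H, seq_len(n), frozen_context = FALSE))
    idx <- as.vector(outer(-2:0, 3L * as.integer(atom_ids), `+`))
    hessian_data(H[idx, idx], atom_ids,
                 frozen_context = length(atom_ids) < n)
  }
  self <- NULL  # filled below; with_bond wraps the compiled closures
  with_bond <- function(i, j, kf, r0) {
    rs <- list(i = as.integer(i), j = as.integer(j), k = kf, r0 = r0)
    out <- self
    out$energy <- function(coords) energy(coords, rs)
    out$gradient <- function(coords) gradient(coords, rs)
    out
  }
  subset_engine <- function(atom_ids, sub_system) {
    atom_ids <- sort(as.integer(atom_ids))
    keep <- terms$ti %in% atom_ids &
      (terms$tj %in% atom_ids | terms$tj == n + 1L)
    keep <- keep & terms$type != .TERM_CONF  # continuum stage: no wall
    remap <- match(seq_len(n), atom_ids)
    t2 <- list(ti = remap[terms$ti[keep]],
               tj = ifelse(terms$tj[keep] > n, length(atom_ids) + 1L,
                           remap[terms$tj[keep]]),
               type = terms$type[keep], p1 = terms$p1[keep],
               p2 = terms$p2[keep], p3 = terms$p3[keep])
    dw2 <- NULL
    if (!is.null(dwell) && all(c(dwell$i, dwell$j) %in% atom_ids))
      dw2 <- list(i = remap[dwell$i], j = remap[dwell$j],
                  h = dwell$h, c = dwell$c, w = dwell$w)
    .toy_engine_from_terms(sub_system, t2, dw2)
  }

  self <- structure(list(energy = energy, gradient = gradient,
                         hessian = hessian, with_bond = with_bond,
                         subset = subset_engine, dwell = dwell, n = n,
                         system = system, terms = terms),
                    class = "toy_engine")
  self
}

#' Minimize the energy over a set of free atoms
#'
#' L-BFGS on the free coordinates with the analytic gradient; frozen
#' atoms' coordinates are bit-for-bit untouched.
#'
#' @param engine A [toy_engine()] (or any object with `energy`/`gradient`
#'   closures over an N x 3 coordinate matrix).
#' @param coords N x 3 starting coordinates (Angstrom).
#' @param free_atoms Atom indices allowed to move (default all).
#' @param gtol Convergence threshold on the maximum absolute gradient
#'   component (Hartree/Angstrom).
#' @param maxit Maximum L-BFGS iterations.
#' @return List with `coords`, `energy`, `grad_max`, `converged`.
#' @export
optimize_structure <- function(engine, coords, free_atoms = NULL,
                               gtol = 3e-4, maxit = 1000) {
  n <- nrow(coords)
  if (is.null(free_atoms)) free_atoms <- seq_len(n)
  free_atoms <- sort(unique(as.integer(free_atoms)))
  if (!length(free_atoms)) {
    g <- engine$gradient(coords)
    return(list(coords = coords, energy = engine$energy(coords),
                grad_max = 0, converged = TRUE))
  }
  unpack <- function(par) {
    X <- coords
    X[free_atoms, ] <- matrix(par, ncol = 3, byrow = TRUE)
    X
  }
  fn <- function(par) engine$energy(unpack(par))
  gr <- function(par) as.vector(t(engine$gradient(unpack(par))[free_atoms, ,
                                                               drop = FALSE]))
  par0 <- as.vector(t(coords[free_atoms, , drop = FALSE]))
  res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4,
                                     pgtol = gtol / 10))
  X <- unpack(res$par)
  gmax <- max(abs(engine$gradient(X)[free_atoms, , drop = FALSE]))
  list(coords = X, energy = res$value, grad_max = gmax,
       converged = gmax <= gtol)
}

#' Refine a first-order saddle point
#'
#' Alternates (a) a transverse relaxation of the free atoms with the
#' engine's reaction coordinate restrained at its current value and (b) a
#' modified Newton step on the free-atom block of the analytic Hessian
#' (near-zero modes skipped, step trust-capped) that walks the reaction
#' coordinate up to the barrier top. Verifies on exit that the gradient is
#' converged and exactly one significantly negative eigenvalue remains.
#'
#' @inheritParams optimize_structure
#' @param gtol Gradient threshold (Hartree/Angstrom).
#' @param trust Maximum Newton step norm per iteration (Angstrom).
#' @param restrain_k Force constant of the transverse-relaxation
#'   restraint.
#' @return List with `coords`, `energy`, `grad_max`, `n_negative`,
#'   `converged`.
#' @export
ts_optimize <- function(engine, coords, free_atoms = NULL, gtol = 1e-7,
                        maxit = 150, trust = 0.15, restrain_k = 5) {
  n <- nrow(coords)
  if (is.null(free_atoms)) free_atoms <- seq_len(n)
  free_atoms <- sort(unique(as.integer(free_atoms)))
  idx <- as.vector(outer(-2:0, 3L * free_atoms, `+`))
  dw <- engine$dwell
  use_restraint <- !is.null(dw) && all(c(dw$i, dw$j) %in% free_atoms)
  X <- coords
  for (it in seq_len(maxit)) {
    g <- as.vector(t(engine$gradient(X)[free_atoms, , drop = FALSE]))
    if (max(abs(g)) <= gtol) break
    if (use_restraint) {
      d_now <- sqrt(sum((X[dw$i, ] - X[dw$j, ])^2))
      drv <- engine$with_bond(dw$i, dw$j, restrain_k, d_now)
      X <- optimize_structure(drv, X, free_atoms = free_atoms,
                              gtol = gtol / 2, maxit = 400)$coords
      g <- as.vector(t(engine$gradient(X)[free_atoms, , drop = FALSE]))
      if (max(abs(g)) <= gtol) break
    }
    Hfull <- engine$hessian(X)$matrix / solv_constants$bohr^2  # back to /A^2
    H <- Hfull[idx, idx]
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- e$values
    keep <- abs(lam) > 1e-6
    coef <- crossprod(e$vectors[, keep, drop = FALSE], g) / lam[keep]
    step <- -as.vector(e$vectors[, keep, drop = FALSE] %*% coef)
    sn <- sqrt(sum(step^2))
    if (sn > trust) step <- step * trust / sn
    X[free_atoms, ] <- X[free_atoms, ] +
      matrix(step, ncol = 3, byrow = TRUE)
  }
  g <- engine$gradient(X)[free_atoms, , drop = FALSE]
  H <- engine$hessian(X)$matrix[idx, idx, drop = FALSE]
  lam <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  nneg <- sum(lam < -1e-6 * max(abs(lam)))
  list(coords = X, energy = engine$energy(X), grad_max = max(abs(g)),
       n_negative = nneg, converged = max(abs(g)) <= gtol && nneg == 1L)
}
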