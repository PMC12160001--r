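# Inertia tensors and van-der-Waals convex-hull volumes.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Principal moments of inertia
#'
#' Eigenvalues of the inertia tensor about the center of mass, in
#' amu Angstrom^2, sorted ascending.
#'
#' @param structure An [atomic_structure()].
#' @return Numeric vector `c(Ia, Ib, Ic)`, ascending, all >= 0.
#' @export
principal_moments <- function(structure) {
  stopifnot(n_atoms(structure) >= 1)
  m <- structure$masses
  x <- structure$coordinates
  com <- colSums(x * m) / sum(m)
  x <- sweep(x, 2, com)
  r2 <- rowSums(x^2)
  I <- diag(sum(m * r2), 3) - crossprod(x * sqrt(m))
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  pmax(ev, 0)
}

#' Deterministic Fibonacci lattice on the unit sphere
#'
#' @param k Number of points.
#' @return A k x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(k) {
  i <- seq_len(k) - 0.5
  z <- 1 - 2 * i / k
  phi <- (seq_len(k) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Canonical right-handed frame from the plain covariance of the atom
# centers; signs fixed by third moments so the frame co-rotates with the
# structure. Makes sphere sampling rotation-covariant.
.canonical_frame <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(diag(3))
  X <- sweep(coords, 2, colMeans(coords))
  C <- crossprod(X) / n
  if (max(abs(C)) < 1e-12) return(diag(3))
  V <- eigen(C, symmetric = TRUE)$vectors
  for (k in 1:2) {
    s <- sum((X %*% V[, k])^3)
    if (abs(s) < 1e-9 * max(1, sum(abs(X %*% V[, k]))^3 / n^2)) {
      j <- which.max(abs(V[, k]))
      s <- V[j, k]
    }
    if (s < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- .cross3(V[, 1], V[, 2])
  V
}

#' Volume of the convex hull of a 3-D point set
#'
#' Quickhull with an interior-point orientation test; returns the enclosed
#' volume. Errors on degenerate (lower-dimensional) input.
#'
#' @param points An n x 3 numeric matrix, n >= 4.
#' @return Hull volume (same cubed units as the coordinates).
#' @export
convex_hull_volume <- function(points) {
  P <- unique(matrix(as.numeric(points), ncol = 3))
  n <- nrow(P)
  if (n < 4) stop("need at least 4 distinct points", call. = FALSE)
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (scale <= 0) stop("degenerate point set", call. = FALSE)
  eps <- 1e-10 * scale

  # --- initial tetrahedron from extreme points
  ext <- unique(c(apply(P, 2, which.min), apply(P, 2, which.max)))
  d12 <- as.matrix(stats::dist(P[ext, , drop = FALSE]))
  ij <- which(d12 == max(d12), arr.ind = TRUE)[1, ]
  p1 <- ext[ij[1]]; p2 <- ext[ij[2]]
  u <- P[p2, ] - P[p1, ]
  w <- sweep(P, 2, P[p1, ])
  cr <- cbind(w[, 2] * u[3] - w[, 3] * u[2],
              w[, 3] * u[1] - w[, 1] * u[3],
              w[, 1] * u[2] - w[, 2] * u[1])
  lin <- sqrt(rowSums(cr^2))
  p3 <- which.max(lin)
  if (lin[p3] <= eps * sqrt(sum(u^2)))
    stop("degenerate (collinear) point set", call. = FALSE)
  nrm0 <- .cross3(P[p2, ] - P[p1, ], P[p3, ] - P[p1, ])
  hts <- abs(w %*% nrm0)
  p4 <- which.max(hts)
  if (hts[p4] <= eps * sqrt(sum(nrm0^2)))
    stop("degenerate (coplanar) point set", call. = FALSE)
  o <- colMeans(P[c(p1, p2, p3, p4), ])

  mk_face <- function(a, b, c) {
    nrm <- .cross3(P[b, ] - P[a, ], P[c, ] - P[a, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    if (sum(nrm * (o - P[a, ])) > 0) { tmp <- b; b <- c; c <- tmp; nrm <- -nrm }
    list(v = c(a, b, c), n = nrm, d = sum(nrm * P[a, ]), out = integer(0))
  }
  faces <- list(mk_face(p1, p2, p3), mk_face(p1, p2, p4),
                mk_face(p1, p3, p4), mk_face(p2, p3, p4))

  assign_points <- function(faces, cand) {
    for (fi in seq_along(faces)) {
      if (!length(cand)) break
      dist <- P[cand, , drop = FALSE] %*% faces[[fi]]$n - faces[[fi]]$d
      above <- dist > eps
      if (any(above)) {
        faces[[fi]]$out <- cand[above]
        cand <- cand[!above]
      }
    }
    faces
  }
  faces <- assign_points(faces, setdiff(seq_len(n), c(p1, p2, p3, p4)))

  repeat {
    fi <- which(lengths(lapply(faces, `[[`, "out")) > 0)[1]
    if (is.na(fi)) break
    f <- faces[[fi]]
    dist <- P[f$out, , drop = FALSE] %*% f$n - f$d
    p <- f$out[which.max(dist)]
    vis <- vapply(faces, function(g) sum(g$n * P[p, ]) - g$d > eps, TRUE)
    vis_faces <- faces[vis]
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(vis_faces, function(g)
      rbind(g$v[c(1, 2)], g$v[c(2, 3)], g$v[c(3, 1)])))
    keys <- paste(edges[, 1], edges[, 2])
    rkeys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rkeys %in% keys), , drop = FALSE]
    cand <- setdiff(unique(unlist(lapply(vis_faces, `[[`, "out"))), p)
    new_faces <- lapply(seq_len(nrow(horizon)), function(k)
      mk_face(horizon[k, 1], horizon[k, 2], p))
    new_faces <- assign_points(new_faces, cand)
    faces <- c(faces[!vis], new_faces)
  }

  vol <- 0
  for (f in faces) {
    A <- P[f$v[1], ] - o; B <- P[f$v[2], ] - o; C <- P[f$v[3], ] - o
    vol <- vol + abs(A %*% .cross3(B, C)) / 6
  }
  as.numeric(vol)
}

#' Van der Waals convex-hull volume of a structure
#'
#' Samples a deterministic Fibonacci lattice of `points_per_atom` points on
#' each atom's van-der-Waals sphere and returns the volume of the convex
#' hull of the sampled cloud. The lattice is laid out in a canonical
#' molecular frame (principal axes of the atom centers), so the result is
#' invariant under rigid rotation and translation of the input.
#'
#' @param structure An [atomic_structure()].
#' @param points_per_atom Points sampled per atom (>= 50, default 256).
#' @return Volume in Angstrom^3.
#' @export
molecular_volume <- function(structure, points_per_atom = 256) {
  stopifnot(n_atoms(structure) >= 1, points_per_atom >= 50)
  dirs <- fibonacci_sphere(points_per_atom)
  frame <- .canonical_frame(structure$coordinates)
  dirs <- dirs %*% t(frame)
  r <- unname(vdw_radius(structure$symbols))
  pts <- do.call(rbind, lapply(seq_len(n_atoms(structure)), function(i)
    sweep(dirs * r[i], 2, structure$coordinates[i, ], `+`)))
  convex_hull_volume(pts)
}
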