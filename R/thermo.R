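# Rigid-rotor / harmonic-oscillator / particle-in-a-box thermochemistry
# and Eyring rates. Energies in kJ/mol, entropies in J/(mol K),
# frequencies in cm^-1.

#' Thermodynamic conditions
#'
#' @param T Temperature in K (default 298.15).
#' @param p Pressure in Pa (default 101325, i.e. 1 atm).
#' @param sigma Rotational symmetry number (default 1: microsolvated
#'   clusters generally have C1 symmetry).
#' @return An object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(T = 298.15, p = 101325, sigma = 1L) {
  stopifnot(T > 0, p > 0, sigma >= 1)
  structure(list(T = T, p = p, sigma = as.integer(sigma)),
            class = "thermo_conditions")
}

#' Translational internal energy and entropy
#'
#' Particle-in-a-box: `U_tra = (3/2) R T` and the Sackur-Tetrode entropy.
#'
#' @param m Total mass in amu.
#' @param cond A [thermo_conditions()].
#' @return List with `U` (kJ/mol) and `S` (J/(mol K)).
#' @export
translational <- function(m, cond = thermo_conditions()) {
  stopifnot(m > 0)
  k <- solv_constants
  mkg <- m * k$amu
  q <- (2 * pi * mkg * k$kB * cond$T / k$h^2)^1.5 * k$kB * cond$T / cond$p
  list(U = 1.5 * k$R * cond$T / 1000, S = k$R * (2.5 + log(q)))
}

#' Rotational internal energy and entropy
#'
#' Rigid rotor. Nonlinear species use all three principal moments; linear
#' species (smallest moment ~ 0) the linear-rotor formula; single atoms
#' contribute nothing.
#'
#' @param moments Principal moments of inertia in amu Angstrom^2 (ascending,
#'   as from [principal_moments()]).
#' @param cond A [thermo_conditions()].
#' @return List with `U` (kJ/mol) and `S` (J/(mol K)).
#' @export
rotational <- function(moments, cond = thermo_conditions()) {
  if (any(moments < -1e-12)) stop("negative moment of inertia", call. = FALSE)
  moments <- sort(pmax(moments, 0))
  k <- solv_constants
  Isi <- moments * k$amu * 1e-20  # amu A^2 -> kg m^2
  tol <- 1e-10 * max(Isi, 1e-60)
  if (Isi[3] <= tol) return(list(U = 0, S = 0))  # single atom
  if (Isi[1] <= tol) {  # linear rotor
    q <- 8 * pi^2 * Isi[3] * k$kB * cond$T / (cond$sigma * k$h^2)
    return(list(U = k$R * cond$T / 1000, S = k$R * (1 + log(q))))
  }
  q <- sqrt(pi) / cond$sigma *
    (8 * pi^2 * k$kB * cond$T / k$h^2)^1.5 * sqrt(prod(Isi))
  list(U = 1.5 * k$R * cond$T / 1000, S = k$R * (1.5 + log(q)))
}

#' Vibrational internal energy and entropy
#'
#' Harmonic oscillators: `U_vib` includes the zero-point energy; `S_vib`
#' is the usual harmonic entropy. Imaginary modes must be excluded
#' upstream.
#'
#' @param frequencies Harmonic wavenumbers in cm^-1, all > 0 (possibly
#'   empty).
#' @param cond A [thermo_conditions()].
#' @return List with `U` (kJ/mol, >= ZPE) and `S` (J/(mol K)).
#' @export
vibrational <- function(frequencies, cond = thermo_conditions()) {
  if (!length(frequencies)) return(list(U = 0, S = 0))
  if (any(frequencies <= 0))
    stop("non-positive frequency at mode ", which(frequencies <= 0)[1],
         call. = FALSE)
  k <- solv_constants
  nu <- frequencies * 100 * k$c              # cm^-1 -> Hz
  x <- k$h * nu / (k$kB * cond$T)
  U <- k$NA_ * k$h * sum(nu * (0.5 + 1 / expm1(x))) / 1000
  S <- k$R * sum(x / expm1(x) - log1p(-exp(-x)))
  list(U = U, S = S)
}

# Project rigid-body translations/rotations out of a mass-weighted Hessian
# and return harmonic wavenumbers (cm^-1; imaginary modes negative).
.harmonic_frequencies <- function(structure, hessian) {
  k <- solv_constants
  n <- n_atoms(structure)
  stopifnot(3L * n == nrow(hessian$matrix))
  m_me <- structure$masses / k$me_amu  # amu -> electron masses
  sm <- rep(sqrt(m_me), each = 3L)
  Hmw <- hessian$matrix / outer(sm, sm)
  # rigid-body basis in mass-weighted coordinates
  com <- colSums(structure$coordinates * structure$masses) /
    sum(structure$masses)
  X <- sweep(structure$coordinates, 2, com) / k$bohr  # Bohr
  B <- matrix(0, 3L * n, 6L)
  for (a in 1:3) B[seq(a, 3L * n, by = 3L), a] <- sqrt(m_me)
  for (i in seq_len(n)) {
    r <- X[i, ]; s <- sqrt(m_me[i]); o <- 3L * (i - 1L)
    B[o + 1:3, 4] <- s * .cross3(c(1, 0, 0), r)
    B[o + 1:3, 5] <- s * .cross3(c(0, 1, 0), r)
    B[o + 1:3, 6] <- s * .cross3(c(0, 0, 1), r)
  }
  qrB <- qr(B)
  Q <- qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
  P <- diag(3L * n) - tcrossprod(Q)
  Hp <- P %*% Hmw %*% P
  # the projection pins qr-rank eigenvalues at (numerically) zero; the
  # remaining 3N - rank eigenvalues are the vibrational ones
  ev_all <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ord <- order(abs(ev_all))
  ev <- sort(ev_all[ord[-seq_len(qrB$rank)]])
  sign(ev) * sqrt(abs(ev)) * k$hartree_cm1
}

#' Thermochemistry of a species from structure, energy and Hessian
#'
#' Projects rigid-body modes out of the mass-weighted full Hessian,
#' converts the remaining eigenvalues to harmonic wavenumbers, discards
#' numerical noise below `noise_cutoff` cm^-1 (with a warning) and, for a
#' transition state, exactly one imaginary mode; then assembles
#' U = E_el + U_tra + U_rot + U_vib, S = S_tra + S_rot + S_vib,
#' H = U + RT (ideal-gas pV) and G = H - T S.
#'
#' @param structure An [atomic_structure()].
#' @param E_el Electronic energy in kJ/mol.
#' @param hessian A full [hessian_data()] matching the structure
#'   (Hartree/Bohr^2).
#' @param cond A [thermo_conditions()].
#' @param is_ts `TRUE` for a transition state (one imaginary mode expected
#'   and discarded from the vibrational sums).
#' @param noise_cutoff Wavenumber magnitude below which modes are treated
#'   as numerical noise (default 5 cm^-1).
#' @return An object of class `species_thermo` with the electronic energy,
#'   real frequencies, component energies/entropies and H, S, G.
#' @export
species_thermo <- function(structure, E_el, hessian,
                           cond = thermo_conditions(), is_ts = FALSE,
                           noise_cutoff = 5) {
  stopifnot(inherits(hessian, "hessian_data"))
  if (hessian$frozen_context)
    stop("species_thermo requires a full Hessian, not a partial one",
         call. = FALSE)
  n <- n_atoms(structure)
  freq <- if (n > 1) .harmonic_frequencies(structure, hessian) else numeric(0)
  noisy <- abs(freq) < noise_cutoff
  if (any(noisy)) {
    warning(sum(noisy), " mode(s) below ", noise_cutoff,
            " cm^-1 discarded as numerical noise")
    freq <- freq[!noisy]
  }
  imag <- freq < 0
  if (is_ts) {
    if (sum(imag) != 1L)
      stop("transition state must have exactly one imaginary mode beyond ",
           "the noise cutoff; found ", sum(imag), call. = FALSE)
  } else if (any(imag)) {
    stop("minimum structure has ", sum(imag), " imaginary mode(s)",
         call. = FALSE)
  }
  real_freq <- freq[!imag]
  tra <- translational(sum(structure$masses), cond)
  mom <- principal_moments(structure)
  rot <- rotational(mom, cond)
  vib <- vibrational(real_freq, cond)
  k <- solv_constants
  U <- E_el + tra$U + rot$U + vib$U
  S <- tra$S + rot$S + vib$S
  H <- U + k$R * cond$T / 1000
  structure(list(E_el = E_el, frequencies = real_freq,
                 imaginary_count = sum(imag),
                 imaginary_frequencies = freq[imag],
                 mass = sum(structure$masses), moments = mom,
                 U_tra = tra$U, U_rot = rot$U, U_vib = vib$U,
                 S_tra = tra$S, S_rot = rot$S, S_vib = vib$S,
                 U = U, H = H, S = S, G = H - cond$T * S / 1000,
                 conditions = cond),
            class = "species_thermo")
}

#' @export
print.species_thermo <- function(x, ...) {
  cat(sprintf(paste0("<species_thermo> %d real modes, %d imaginary | ",
                     "H = %.3f kJ/mol, S = %.3f J/(mol K), G = %.3f kJ/mol\n"),
              length(x$frequencies), x$imaginary_count, x$H, x$S, x$G))
  invisible(x)
}

#' Activation quantities between a reactant and a transition state
#'
#' Translational contributions cancel exactly (same atoms, same mass) and
#' the pV terms drop out, so `dH = dE_el + dU_vib` and
#' `dS = dS_rot + dS_vib`; `dG = dH - T dS`. The Eyring rate at the
#' conditions' temperature is attached.
#'
#' @param reactant,ts [species_thermo()] objects computed at the same
#'   conditions.
#' @param cond A [thermo_conditions()]; must match both species.
#' @return An object of class `activation_result` with `dE_el`, `dU_vib`,
#'   `dH` (kJ/mol), `dS_rot`, `dS_vib`, `dS` (J/(mol K)), `dG` (kJ/mol)
#'   and `rate` (1/s).
#' @export
activation <- function(reactant, ts, cond = reactant$conditions) {
  same <- function(a, b) isTRUE(all.equal(a[c("T", "p", "sigma")],
                                          b[c("T", "p", "sigma")]))
  if (!same(reactant$conditions, cond) || !same(ts$conditions, cond))
    stop("reactant and TS must share the same thermodynamic conditions",
         call. = FALSE)
  dE_el <- ts$E_el - reactant$E_el
  dU_vib <- ts$U_vib - reactant$U_vib
  dH <- dE_el + dU_vib
  dS_rot <- ts$S_rot - reactant$S_rot
  dS_vib <- ts$S_vib - reactant$S_vib
  dS <- dS_rot + dS_vib
  dG <- dH - cond$T * dS / 1000
  structure(list(dE_el = dE_el, dU_vib = dU_vib, dH = dH,
                 dS_rot = dS_rot, dS_vib = dS_vib, dS = dS, dG = dG,
                 rate = eyring_rate(dG, cond$T), conditions = cond),
            class = "activation_result")
}

#' Eyring rate constant
#'
#' `k = (k_B T / h) exp(-dG / (R T))`.
#'
#' @param dG Free energy of activation in kJ/mol.
#' @param T Temperature in K.
#' @return Rate constant in 1/s.
#' @export
eyring_rate <- function(dG, T = 298.15) {
  stopifnot(T > 0)
  k <- solv_constants
  k$kB * T / k$h * exp(-dG * 1000 / (k$R * T))
}
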