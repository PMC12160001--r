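# A minimal analytic "proton shuttle" reactive complex used by the
# pipeline tests and examples: a proton between two oxygen-like centers,
# with a double-well along the donor-proton distance. The saddle location
# is known in closed form (all bonds at rest length, the double-well
# coordinate at its barrier top).

#' Toy reactive complex and its potential terms
#'
#' Three atoms O-H...O: a harmonic O-O frame bond, a harmonic
#' acceptor-H bond, and a double-well on the donor-H distance with minima
#' at `c - w` and `c + w` and barrier height `h`. At the saddle the
#' donor-H distance equals `c` and the Hessian has exactly one negative
#' eigenvalue.
#'
#' @param h Barrier height of the double well (Hartree, default 0.02,
#'   about 52 kJ/mol).
#' @param c_dw Barrier-top donor-H distance (Angstrom).
#' @param w Half-separation of the two minima (Angstrom).
#' @return List with `structure` (an [atomic_structure()] placed at the
#'   reactant minimum), `bonds`, `dwell`, `reactive_atoms`,
#'   `active_atoms`, and `saddle_dw` (the saddle value of the double-well
#'   coordinate).
#' @export
toy_reaction <- function(h = 0.02, c_dw = 1.2, w = 0.2) {
  d_OO <- 2.2; d_HA <- 1.3
  d1 <- c_dw - w  # reactant donor-H distance
  x <- (d1^2 - d_HA^2 + d_OO^2) / (2 * d_OO)
  y <- sqrt(max(0, d1^2 - x^2))
  st <- atomic_structure(c("O", "H", "O"),
                         rbind(c(0, 0, 0), c(x, y, 0), c(d_OO, 0, 0)),
                         comment = "toy proton-shuttle complex")
  list(structure = st,
       bonds = data.frame(i = c(1L, 2L), j = c(3L, 3L),
                          k = c(0.5, 0.4), r0 = c(d_OO, d_HA)),
       dwell = list(i = 1L, j = 2L, h = h, c = c_dw, w = w),
       reactive_atoms = 1:3, active_atoms = c(1L, 3L),
       saddle_dw = c_dw)
}

#' Build the droplet system and engine for a toy pipeline trial
#'
#' Assembles a seeded water microdroplet around the [toy_reaction()]
#' complex and a [toy_engine()] over it (solvent rigid bonds,
#' intermolecular repulsion, flat-bottom confinement at the outer shell).
#'
#' @param n_solvent Number of water molecules.
#' @param seed RNG seed for the droplet placement.
#' @param reaction A [toy_reaction()] description.
#' @param shell_radii Optional shell radii passed to [droplet_config()].
#' @return List with `system` ([molecular_system()]) and `engine`
#'   ([toy_engine()]).
#' @export
toy_trial_setup <- function(n_solvent = 8, seed = 1,
                            reaction = toy_reaction(),
                            shell_radii = NULL) {
  cfg <- droplet_config(n_solvent = n_solvent, seed = seed,
                        shell_radii = shell_radii)
  sys <- make_droplet(reaction$structure, cfg,
                      reactive_atoms = reaction$reactive_atoms,
                      active_atoms = reaction$active_atoms)
  R_conf <- max(sqrt(rowSums(sys$structure$coordinates^2))) + 1
  eng <- toy_engine(sys, bonds = reaction$bonds, dwell = reaction$dwell,
                    confinement = list(k = 0.01, R = R_conf))
  list(system = sys, engine = eng, reaction = reaction)
}
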