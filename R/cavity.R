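# Scaled-particle-style cavity-formation work and the cavity-entropy
# correction to the free energy of activation. The solvent enters only
# through its relative permittivity (via the packing fraction) and its
# molecular volume (via the radius ratio).

#' Solvent specification
#'
#' @param name Solvent name.
#' @param relative_permittivity Relative permittivity (>= 1).
#' @param molecular_volume Molecular van-der-Waals hull volume in
#'   Angstrom^3.
#' @param template_geometry Optional [atomic_structure()] template.
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(name, relative_permittivity, molecular_volume,
                         template_geometry = NULL) {
  stopifnot(relative_permittivity >= 1, molecular_volume > 0)
  structure(list(name = name,
                 relative_permittivity = relative_permittivity,
                 molecular_volume = molecular_volume,
                 template_geometry = template_geometry),
            class = "solvent_spec")
}

#' Load a packaged solvent
#'
#' Reads the shipped solvent database (plain text: name, relative
#' permittivity at 20 C, molecular volume) and the corresponding template
#' geometry.
#'
#' @param name `"water"` or `"methanol"`.
#' @return A [solvent_spec()].
#' @export
load_solvent <- function(name) {
  path <- system.file("extdata", "solvents.tsv", package = "solvmode",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1)
    stop("unknown solvent: ", name, " (have: ",
         paste(tab$name, collapse = ", "), ")", call. = FALSE)
  tpl <- read_xyz(system.file("extdata", row$template,
                              package = "solvmode", mustWork = TRUE))
  solvent_spec(name, row$epsilon_r, row$volume, tpl)
}

#' Packing fraction from the relative permittivity
#'
#' `y = (3 / 4 pi) (eps_r - 1) / (eps_r + 2)`; 0 in vacuum, approaching
#' `3/(4 pi)` in the conductor limit.
#'
#' @param eps_r Relative permittivity (>= 1).
#' @return Packing fraction in `[0, 3/(4 pi))`.
#' @export
packing_fraction <- function(eps_r) {
  if (any(eps_r < 1)) stop("relative permittivity must be >= 1",
                           call. = FALSE)
  3 / (4 * pi) * (eps_r - 1) / (eps_r + 2)
}

#' Solute/solvent radius ratio
#'
#' `R_s = (V_solute / V_solvent)^(1/3)`. The ratio is meaningful as long as
#' both volumes are determined with the same convention (here: van der
#' Waals convex hulls).
#'
#' @param V_solute,V_solvent Volumes in Angstrom^3 (> 0).
#' @return Dimensionless radius ratio.
#' @export
radius_ratio <- function(V_solute, V_solvent) {
  if (any(V_solute <= 0) || any(V_solvent <= 0))
    stop("volumes must be positive", call. = FALSE)
  (V_solute / V_solvent)^(1 / 3)
}

#' Dimensionless cavity-formation work
#'
#' Scaled-particle expression in units of RT:
#' `g_c = -log(1-y) + R_s 3y/(1-y) + R_s^2 (3y/(1-y) + (9/2)(y/(1-y))^2)`.
#'
#' @param y Packing fraction in `[0, 1)`.
#' @param R_s Radius ratio (>= 0).
#' @return Dimensionless cavity work (>= 0).
#' @export
cavity_work <- function(y, R_s) {
  if (any(y < 0) || any(y >= 1)) stop("packing fraction must be in [0, 1)",
                                      call. = FALSE)
  if (any(R_s < 0)) stop("radius ratio must be >= 0", call. = FALSE)
  t <- y / (1 - y)
  -log1p(-y) + R_s * 3 * t + R_s^2 * (3 * t + 4.5 * t^2)
}

.effective_solvent <- function(solvent) {
  if (inherits(solvent, "mixture_spec"))
    list(eps = solvent$effective_eps_r, V = solvent$effective_V)
  else if (inherits(solvent, "solvent_spec"))
    list(eps = solvent$relative_permittivity, V = solvent$molecular_volume)
  else stop("solvent must be a solvent_spec or mixture_spec", call. = FALSE)
}

#' Cavity entropy of a species in a solvent
#'
#' `S_c = G_c / T` with `G_c = R T g_c`, i.e. `S_c = R g_c`; the
#' temperature cancels unless a temperature-dependent permittivity is
#' supplied upstream.
#'
#' @param species_volume Van-der-Waals hull volume of the species in
#'   Angstrom^3.
#' @param solvent A [solvent_spec()] or [mixture_effective()] result.
#' @param T Temperature in K (only used to report `G_c`).
#' @return List with `S_c` (J/(mol K)), `G_c` (kJ/mol), `y`, `R_s`, `g_c`.
#' @export
cavity_entropy <- function(species_volume, solvent, T = 298.15) {
  eff <- .effective_solvent(solvent)
  y <- packing_fraction(eff$eps)
  R_s <- radius_ratio(species_volume, eff$V)
  g <- cavity_work(y, R_s)
  k <- solv_constants
  list(S_c = k$R * g, G_c = k$R * T * g / 1000, y = y, R_s = R_s, g_c = g)
}

#' Change in cavity entropy of activation
#'
#' `dS_c = S_c(TS) - (sum_i S_c(R'_i) + n S_c(L))`: only the cavity
#' entropies of the transition state, of the isolated solute fragments
#' R'_i and of a single solvent molecule L are needed; the entropies of
#' the assembled reactant cluster telescope out.
#'
#' @param ts_volume Hull volume of the TS cluster (Angstrom^3).
#' @param fragment_volumes Hull volumes of the isolated solute fragments.
#' @param n_solvent Number of explicit solvent molecules in the cluster.
#' @param solvent A [solvent_spec()] or mixture.
#' @param T Temperature in K.
#' @return `dS_c` in J/(mol K) with attribute `"parts"` carrying the
#'   per-species cavity entropies.
#' @export
delta_Sc_activation <- function(ts_volume, fragment_volumes, n_solvent = 0,
                                solvent, T = 298.15) {
  if (!length(fragment_volumes))
    stop("at least one solute fragment volume is required", call. = FALSE)
  stopifnot(n_solvent >= 0)
  eff <- .effective_solvent(solvent)
  S_ts <- cavity_entropy(ts_volume, solvent, T)$S_c
  S_frag <- vapply(fragment_volumes,
                   function(v) cavity_entropy(v, solvent, T)$S_c, 1.0)
  S_L <- if (n_solvent > 0) cavity_entropy(eff$V, solvent, T)$S_c else 0
  out <- S_ts - (sum(S_frag) + n_solvent * S_L)
  attr(out, "parts") <- list(S_c_TS = S_ts, S_c_fragments = S_frag,
                             S_c_solvent = S_L, n_solvent = n_solvent)
  out
}

#' Cavity-corrected Gibbs free energy of activation
#'
#' `dG_c = dG - T dS_c`; a negative cavity entropy of activation raises
#' the barrier.
#'
#' @param dG Free energy of activation in kJ/mol.
#' @param dS_c Cavity entropy of activation in J/(mol K).
#' @param T Temperature in K.
#' @return Corrected barrier in kJ/mol.
#' @export
corrected_gibbs <- function(dG, dS_c, T = 298.15) {
  dG - T * as.numeric(dS_c) / 1000
}

#' Effective parameters of a solvent mixture
#'
#' Mole-fraction-weighted arithmetic means of the relative permittivity
#' and the molecular volume.
#'
#' @param components List of `list(spec = solvent_spec, fraction = x)`
#'   entries; fractions must sum to 1.
#' @return An object of class `mixture_spec` with `components`,
#'   `effective_eps_r` and `effective_V`.
#' @export
mixture_effective <- function(components) {
  fr <- vapply(components, function(cm) cm$fraction, 1.0)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", sum(fr), ")", call. = FALSE)
  eps <- vapply(components, function(cm) cm$spec$relative_permittivity, 1.0)
  V <- vapply(components, function(cm) cm$spec$molecular_volume, 1.0)
  structure(list(components = components,
                 effective_eps_r = sum(fr * eps),
                 effective_V = sum(fr * V)),
            class = "mixture_spec")
}
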