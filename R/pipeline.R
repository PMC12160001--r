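# Three-stage orchestration: lQM/MM TS-guess extraction, mQM/MM minimum
# energy path, sQM continuum-stage thermochemistry with cavity-entropy
# correction. The engine is pluggable; the shipped reference engine is
# the analytic toy potential.

#' Pipeline configuration
#'
#' @param lqm_rc Fixed lQM sphere radius in Angstrom (default 4.5).
#' @param lqm_passes Number of loosened lQM relaxation passes with region
#'   redefinition in between (default 2).
#' @param loose_factor Multiplier on the convergence thresholds for the
#'   lQM passes (default 10).
#' @param mqm_s,sqm_s Scaling factors of the type-dependent sphere radii
#'   for the mQM and sQM stages (defaults 2.3 and 2.0).
#' @param score_weights Weights of `w_norm` and `C` in the mode score.
#' @param threshold_factor Contribution threshold factor on `c_min`.
#' @param mass_power Mass-weighting exponent for the mode analysis.
#' @param gtol Base gradient convergence threshold (Hartree/Angstrom,
#'   default 3e-4).
#' @param ts_gtol Gradient threshold for saddle refinement.
#' @param conditions [thermo_conditions()] for the thermochemistry.
#' @param solvent [solvent_spec()] or mixture for the cavity correction.
#' @param points_per_atom Sphere sampling for hull volumes (default 128).
#' @param nt_steps Number of drive steps of the TS-guess search.
#' @param drive_k Force constant of the driving restraint.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(lqm_rc = 4.5, lqm_passes = 2, loose_factor = 10,
                            mqm_s = 2.3, sqm_s = 2.0,
                            score_weights = c(0.5, 0.5),
                            threshold_factor = 1.0, mass_power = 1,
                            gtol = 3e-4, ts_gtol = 1e-7,
                            conditions = thermo_conditions(),
                            solvent = load_solvent("water"),
                            points_per_atom = 128,
                            nt_steps = 8, drive_k = 2.0) {
  structure(list(lqm_rc = lqm_rc, lqm_passes = lqm_passes,
                 loose_factor = loose_factor, mqm_s = mqm_s, sqm_s = sqm_s,
                 score_weights = score_weights,
                 threshold_factor = threshold_factor,
                 mass_power = mass_power, gtol = gtol, ts_gtol = ts_gtol,
                 conditions = conditions, solvent = solvent,
                 points_per_atom = points_per_atom,
                 nt_steps = nt_steps, drive_k = drive_k),
            class = "pipeline_config")
}

.dw_distance <- function(coords, dwell)
  sqrt(sum((coords[dwell$i, ] - coords[dwell$j, ])^2))

#' Stage 1: lQM/MM transition-state guess extraction
#'
#' MM-relaxes the solvent with the reactive complex frozen, builds the
#' fixed-radius lQM region, runs the loosened lQM relaxation passes with
#' region redefinition, drives the double-well coordinate to its barrier
#' top (the toy stand-in for a single-ended elementary-step search) and
#' computes the partial lQM Hessian with the MM region frozen.
#'
#' @param system A [molecular_system()].
#' @param engine A [toy_engine()] (or adapter with the same contract).
#' @param config A [pipeline_config()].
#' @return A `stage_record` list: `stage`, `region`, `coords`
#'   (TS guess), `hessian` (partial), `energies`, `success`.
#' @export
run_stage1 <- function(system, engine, config = pipeline_config()) {
  X0 <- system$structure$coordinates
  solute <- solute_atoms_of(system$partition)
  solvent_atoms <- setdiff(seq_len(nrow(X0)), solute)
  # MM relaxation, reactive complex frozen
  mm <- optimize_structure(engine, X0, free_atoms = solvent_atoms,
                           gtol = config$gtol)
  X <- mm$coords
  region <- stage_region(system, "lQM",
                         policy = radius_policy("fixed", r_c = config$lqm_rc))
  # loosened lQM relaxation passes with region redefinition in between
  for (pass in seq_len(config$lqm_passes)) {
    free <- setdiff(region$atom_ids, solute)
    if (length(free)) {
      opt <- optimize_structure(engine, X, free_atoms = free,
                                gtol = config$gtol * config$loose_factor)
      X <- opt$coords
    }
    sys_now <- .with_coords(system, X)
    region <- stage_region(sys_now, "lQM",
                           policy = radius_policy("fixed",
                                                  r_c = config$lqm_rc))
  }
  # single-ended drive of the double-well coordinate to the barrier top
  dwell <- engine$dwell
  if (is.null(dwell))
    stop("engine has no designated reaction coordinate", call. = FALSE)
  d_now <- .dw_distance(X, dwell)
  targets <- seq(d_now, dwell$c, length.out = config$nt_steps + 1L)[-1]
  free <- region$atom_ids
  for (lam in targets) {
    drv <- engine$with_bond(dwell$i, dwell$j, config$drive_k, lam)
    X <- optimize_structure(drv, X, free_atoms = free,
                            gtol = config$gtol * config$loose_factor)$coords
  }
  hess <- engine$hessian(X, atom_ids = region$atom_ids)
  list(stage = "1-lQM", region = region, coords = X, hessian = hess,
       coords_init = X0, coords_mm = mm$coords,
       energies = list(E_guess = engine$energy(X)), success = TRUE)
}

.with_coords <- function(system, coords) {
  st <- system$structure
  st$coordinates <- coords
  system$structure <- st
  system
}

# Extract the substructure, partition, reactive/active sets of a region
.sub_system <- function(system, atom_ids) {
  atom_ids <- sort(as.integer(atom_ids))
  st <- system$structure
  sub <- atomic_structure(st$symbols[atom_ids],
                          st$coordinates[atom_ids, , drop = FALSE],
                          masses = st$masses[atom_ids],
                          charge = st$charge, multiplicity = st$multiplicity)
  remap <- match(seq_len(n_atoms(st)), atom_ids)
  mols <- lapply(system$partition$molecules, function(m) {
    mm <- remap[m]
    mm[!is.na(mm)]
  })
  keep <- lengths(mols) > 0
  old_ids <- which(keep)
  part <- molecule_partition(mols[keep],
                             solute_ids = match(
                               intersect(system$partition$solute_ids, old_ids),
                               old_ids),
                             n_atoms = length(atom_ids))
  molecular_system(sub, part,
                   reactive_atoms = remap[system$reactive_atoms],
                   active_atoms = stats::na.omit(remap[system$active_atoms]))
}

#' Stage 2: mQM/MM minimum energy path
#'
#' Analyzes the lQM partial Hessian to find the relevant atoms, builds
#' the mQM region (scaled radii), relaxes the MM region with the mQM
#' atoms frozen, recomputes the partial Hessian, refines the TS following
#' the selected mode, runs the downhill paths to both end points,
#' optimizes them, and disassembles the reactant-side end point into its
#' covalently bound molecules (each optimized in isolation).
#'
#' @param record Stage-1 `stage_record`.
#' @inheritParams run_stage1
#' @return A `stage_record` with fields `region`, `coords` (TS),
#'   `mode_report`, `endpoints`, `fragments`, `energies` (incl.
#'   `dE_el` in kJ/mol), `success`.
#' @export
run_stage2 <- function(record, system, engine, config = pipeline_config()) {
  sys_now <- .with_coords(system, record$coords)
  ana1 <- analyze_modes(record$hessian, sys_now,
                        threshold_factor = config$threshold_factor,
                        weights = config$score_weights,
                        mass_power = config$mass_power)
  region <- stage_region(sys_now, "mQM", ana1$report$relevant_atoms,
                         policy = radius_policy("scaled", s = config$mqm_s))
  n <- nrow(record$coords)
  mm_atoms <- setdiff(seq_len(n), region$atom_ids)
  X_relaxed <- optimize_structure(engine, record$coords,
                                  free_atoms = mm_atoms,
                                  gtol = config$gtol)$coords
  ts <- ts_optimize(engine, X_relaxed, free_atoms = region$atom_ids,
                    gtol = config$ts_gtol)
  if (!ts$converged)
    stop("mQM TS optimization did not converge to a first-order saddle",
         call. = FALSE)
  X <- ts$coords
  hess <- engine$hessian(X, atom_ids = region$atom_ids)
  sys_ts <- .with_coords(system, X)
  ana2 <- analyze_modes(hess, sys_ts,
                        threshold_factor = config$threshold_factor,
                        weights = config$score_weights,
                        mass_power = config$mass_power)
  # downhill paths from the TS along the selected mode
  mode_vec <- ana2$modes$vectors[, ana2$selected_mode]
  ends <- lapply(c(-1, 1), function(sgn)
    .descend_to_minimum(engine, X, region$atom_ids, mode_vec, sgn,
                        config$gtol / 10))
  dw <- engine$dwell
  d_end <- vapply(ends, function(e) .dw_distance(e$coords, dw), 1.0)
  reactant_side <- which.min(d_end)  # lower donor-H distance = reactant
  reactant <- ends[[reactant_side]]
  product <- ends[[-reactant_side + 3L]]
  fragments <- .disassemble_and_optimize(sys_ts, engine, region$atom_ids,
                                         reactant$coords, config)
  dE_el <- (engine$energy(X) - reactant$energy) *
    solv_constants$hartree_kjmol
  list(stage = "2-mQM", region = region, coords = X, hessian = hess,
       coords_relaxed = X_relaxed,
       mode_report = ana2$report, scores = ana2$scores,
       endpoints = list(reactant = reactant, product = product),
       fragments = fragments,
       energies = list(E_ts = engine$energy(X), E_reactant = reactant$energy,
                       dE_el = dE_el),
       success = TRUE)
}

.descend_to_minimum <- function(engine, X, free_atoms, mode_vec, sgn,
                                gtol, delta = 0.1, sd_steps = 30,
                                sd_step = 0.05) {
  idx3 <- as.vector(outer(-2:0, 3L * sort(as.integer(free_atoms)), `+`))
  v <- mode_vec / sqrt(sum(mode_vec^2))
  Xd <- X
  Xd[sort(free_atoms), ] <- Xd[sort(free_atoms), ] +
    sgn * delta * matrix(v, ncol = 3, byrow = TRUE)
  # damped steepest descent to commit to the valley
  step <- sd_step
  e_prev <- engine$energy(Xd)
  for (it in seq_len(sd_steps)) {
    g <- engine$gradient(Xd)
    gmax <- max(abs(g[free_atoms, ]))
    if (gmax < gtol) break
    Xn <- Xd
    Xn[free_atoms, ] <- Xd[free_atoms, ] -
      step * g[free_atoms, ] / max(gmax, 1e-12)
    e_new <- engine$energy(Xn)
    if (e_new < e_prev) { Xd <- Xn; e_prev <- e_new; step <- step * 1.1 }
    else step <- step / 2
  }
  opt <- optimize_structure(engine, Xd, free_atoms = free_atoms,
                            gtol = gtol)
  out <- opt
  if (!opt$converged)
    out <- .newton_minimize(engine, opt$coords, free_atoms, gtol)
  list(coords = out$coords, energy = out$energy, converged = out$converged)
}

# Quadratic-convergence polish for minima: modified Newton with curvature
# floored positive and near-zero (rigid-body) modes skipped.
.newton_minimize <- function(engine, coords, free_atoms, gtol,
                             maxit = 30, trust = 0.2) {
  free_atoms <- sort(as.integer(free_atoms))
  idx <- as.vector(outer(-2:0, 3L * free_atoms, `+`))
  X <- coords
  for (it in seq_len(maxit)) {
    g <- as.vector(t(engine$gradient(X)[free_atoms, , drop = FALSE]))
    if (max(abs(g)) <= gtol) break
    H <- engine$hessian(X)$matrix[idx, idx] / solv_constants$bohr^2
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    keep <- abs(e$values) > 1e-7
    lam <- pmax(abs(e$values[keep]), 1e-4)
    coef <- crossprod(e$vectors[, keep, drop = FALSE], g) / lam
    step <- -as.vector(e$vectors[, keep, drop = FALSE] %*% coef)
    sn <- sqrt(sum(step^2))
    if (sn > trust) step <- step * trust / sn
    X[free_atoms, ] <- X[free_atoms, ] + matrix(step, ncol = 3,
                                                byrow = TRUE)
  }
  g <- engine$gradient(X)[free_atoms, , drop = FALSE]
  list(coords = X, energy = engine$energy(X), grad_max = max(abs(g)),
       converged = max(abs(g)) <= gtol)
}

.disassemble_and_optimize <- function(system, engine, region_atoms,
                                      coords, config) {
  sub_sys <- .sub_system(.with_coords(system, coords), region_atoms)
  mols <- sub_sys$partition$molecules
  region_atoms <- sort(as.integer(region_atoms))
  lapply(seq_along(mols), function(k) {
    gids <- region_atoms[mols[[k]]]
    msys <- .sub_system(.with_coords(system, coords), gids)
    meng <- engine$subset(gids, msys)
    opt <- optimize_structure(meng, msys$structure$coordinates,
                              gtol = config$gtol / 10)
    st <- msys$structure
    st$coordinates <- opt$coords
    list(structure = st, energy = opt$energy,
         is_solute = k %in% sub_sys$partition$solute_ids,
         atom_ids = gids)
  })
}

#' Stage 3: sQM continuum stage with thermochemistry and cavity entropy
#'
#' Analyzes the mQM TS Hessian, builds the sQM region (scaled radii,
#' s = 2.0), extracts the sQM cluster as an isolated subsystem, refines
#' its TS, walks downhill to the reactant-side minimum, and evaluates the
#' free-energy model: RRHO activation quantities, the cavity-entropy
#' correction from convex-hull volumes and the Eyring rate.
#'
#' @param record Stage-2 `stage_record`.
#' @inheritParams run_stage1
#' @return A `stage_record` with `region`, `n_active`, `thermo`
#'   (reactant/ts [species_thermo()]), `activation`, `cavity`
#'   (`dS_c`, `dG_c`), `energies` (`dE_el`, `dG`, `dG_c`), `success`.
#' @export
run_stage3 <- function(record, system, engine, config = pipeline_config()) {
  sys_ts <- .with_coords(system, record$coords)
  ana <- analyze_modes(record$hessian, sys_ts,
                       threshold_factor = config$threshold_factor,
                       weights = config$score_weights,
                       mass_power = config$mass_power)
  region <- stage_region(sys_ts, "sQM", ana$report$relevant_atoms,
                         policy = radius_policy("scaled", s = config$sqm_s))
  sqm_sys <- .sub_system(sys_ts, region$atom_ids)
  sqm_eng <- engine$subset(region$atom_ids, sqm_sys)
  ts <- ts_optimize(sqm_eng, sqm_sys$structure$coordinates,
                    gtol = config$ts_gtol)
  if (!ts$converged)
    stop("sQM TS optimization did not converge to a first-order saddle",
         call. = FALSE)
  sqm_ts_sys <- .with_coords(sqm_sys, ts$coords)
  hess_ts <- sqm_eng$hessian(ts$coords)
  ana_sqm <- analyze_modes(hess_ts, sqm_ts_sys,
                           threshold_factor = config$threshold_factor,
                           weights = config$score_weights,
                           mass_power = config$mass_power)
  mode_vec <- ana_sqm$modes$vectors[, ana_sqm$selected_mode]
  ends <- lapply(c(-1, 1), function(sgn)
    .descend_to_minimum(sqm_eng, ts$coords,
                        seq_len(n_atoms(sqm_sys$structure)), mode_vec, sgn,
                        config$ts_gtol * 10))
  dw <- sqm_eng$dwell
  if (is.null(dw))
    stop("sQM subsystem lost the reaction coordinate", call. = FALSE)
  d_end <- vapply(ends, function(e) .dw_distance(e$coords, dw), 1.0)
  reactant <- ends[[which.min(d_end)]]
  if (!reactant$converged)
    stop("sQM reactant optimization did not converge", call. = FALSE)
  sqm_r_sys <- .with_coords(sqm_sys, reactant$coords)
  hess_r <- sqm_eng$hessian(reactant$coords)
  kjm <- solv_constants$hartree_kjmol
  th_r <- suppressWarnings(
    species_thermo(sqm_r_sys$structure, reactant$energy * kjm, hess_r,
                   cond = config$conditions))
  th_ts <- suppressWarnings(
    species_thermo(sqm_ts_sys$structure, ts$energy * kjm, hess_ts,
                   cond = config$conditions, is_ts = TRUE))
  act <- activation(th_r, th_ts, config$conditions)
  # cavity correction: isolated solute fragments + n solvent molecules -> TS
  frags <- .disassemble_and_optimize(sys_ts, engine, region$atom_ids,
                                     reactant$coords, config)
  solute_frags <- Filter(function(f) f$is_solute, frags)
  n_solv <- sum(!vapply(frags, function(f) f$is_solute, TRUE))
  V_ts <- molecular_volume(sqm_ts_sys$structure, config$points_per_atom)
  V_frag <- vapply(solute_frags, function(f)
    molecular_volume(f$structure, config$points_per_atom), 1.0)
  dS_c <- delta_Sc_activation(V_ts, V_frag, n_solv, config$solvent,
                              T = config$conditions$T)
  dG_c <- corrected_gibbs(act$dG, dS_c, config$conditions$T)
  list(stage = "3-sQM", region = region, coords = ts$coords,
       sqm_atom_ids = sort(region$atom_ids),
       n_active = ana_sqm$report$n_active, mode_report = ana_sqm$report,
       thermo = list(reactant = th_r, ts = th_ts), activation = act,
       cavity = list(dS_c = as.numeric(dS_c), dG_c = dG_c, V_ts = V_ts,
                     V_fragments = V_frag, n_solvent = n_solv),
       energies = list(dE_el = act$dE_el, dG = act$dG, dG_c = dG_c),
       success = TRUE)
}

#' Run one full three-stage trial
#'
#' Assembles a seeded droplet around the toy reactive complex, runs the
#' three stages, and returns either the stage-3 record (with the stage-1
#' and stage-2 records attached) or a failure record carrying the stage
#' and cause. Failed trials are data, not exceptions.
#'
#' @param seed Integer seed controlling the solvent placement.
#' @param n_solvent Number of water molecules in the droplet.
#' @param config A [pipeline_config()].
#' @param setup Optional pre-built `list(system, engine)` overriding the
#'   toy setup.
#' @return A list with `seed`, `success`, and on success `stage1`,
#'   `stage2`, `stage3`; on failure `failed_stage` and `error`.
#' @export
run_trial <- function(seed, n_solvent = 8, config = pipeline_config(),
                      setup = NULL) {
  if (is.null(setup)) setup <- toy_trial_setup(n_solvent = n_solvent,
                                               seed = seed)
  out <- list(seed = seed, success = FALSE)
  stage <- "1-lQM"
  res <- tryCatch({
    s1 <- run_stage1(setup$system, setup$engine, config)
    stage <- "2-mQM"
    s2 <- run_stage2(s1, setup$system, setup$engine, config)
    stage <- "3-sQM"
    s3 <- run_stage3(s2, setup$system, setup$engine, config)
    list(stage1 = s1, stage2 = s2, stage3 = s3)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    out$failed_stage <- stage
    out$error <- conditionMessage(res)
  } else {
    out <- c(out, res)
    out$success <- TRUE
  }
  out
}

#' Five-number summaries of barrier quantities grouped by active-solvent count
#'
#' @param records List of trial records from [run_trial()].
#' @param quantity One of `"dG_c"`, `"dG"`, `"dE_el"` (kJ/mol).
#' @return A data.frame with one row per `n_active` group: `n_active`,
#'   `count`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_ensemble <- function(records, quantity = c("dG_c", "dG", "dE_el")) {
  quantity <- match.arg(quantity)
  ok <- Filter(function(r) isTRUE(r$success), records)
  if (!length(ok)) stop("no successful trials to summarize", call. = FALSE)
  n_act <- vapply(ok, function(r) r$stage3$n_active, 1L)
  val <- vapply(ok, function(r) r$stage3$energies[[quantity]], 1.0)
  groups <- sort(unique(n_act))
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- val[n_act == g]
    q <- stats::fivenum(v)
    data.frame(n_active = g, count = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  }))
  rownames(out) <- NULL
  out
}
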