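---
title: "Staged microsolvation models and cavity-corrected activation free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged microsolvation models and cavity-corrected activation free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvmode)
```

## The problem

Solvent molecules are not always spectators: proton shuttles, hydrogen-bond
relays and ion stabilization can change both the mechanism and the barrier
of a reaction in solution. A cluster–continuum model keeps the few solvent
molecules that matter explicitly and delegates the rest to a dielectric
continuum — but choosing *which* molecules to keep by hand is biased and
does not scale to automated exploration of many reaction trials. `solvmode`
implements a staged, criterion-driven selection and the accompanying
free-energy model.

## Region construction

A QM region is a union of spheres around designated *reactive* atoms (bond
forming/breaking) and *active* atoms (expected solute–solvent contact
points). Two radius policies exist:

* **fixed** — one radius `r_c` for all centers; the large-region default is
  4.5 Å, big enough to leave the selection of participating solvent
  molecules to later, unbiased analysis;
* **scaled** — `r_s = s (r_cov,center + r_cov,probe)`, type-dependent
  through the covalent radii. The probe defaults to hydrogen, which suits
  protic solvents; for, say, dichloromethane one would use Cl. Stage
  defaults are `s = 2.3` (medium region) and `s = 2.0` (small region).
  Larger `s` grows regions monotonically (we assert this over
  `s ∈ {2.0, 2.3, 2.6, 2.9, 3.2}`); the medium-stage default keeps regions
  small enough for routine saddle-point refinement while still capturing
  multi-solvent participation.

Membership is a closed inequality (an atom exactly on the sphere surface is
inside — the tie-break matters for reproducibility and is tested), every
atom of the reactive complex is always included, and solvent molecules are
never split: one atom inside pulls the whole molecule in. Distances are
plain Euclidean; there are no periodic boundaries.

## Selecting the reaction-coordinate mode

Transition-state character lives in the eigenvectors of the
non-mass-weighted Hessian with negative eigenvalues (the saddle-refinement
algorithms this package orchestrates operate on that matrix, so the
analysis does too). For each such mode the vector is mass-weighted
*elementwise by the atomic mass* (`n ⊙ m`), normalized, and two bounded
quantities are combined into a score:

* `w_norm = w / w_min ∈ [0, 1]` — curvature relative to the most negative
  eigenvalue;
* `C ∈ [0, 1]` — the summed squared amplitude on the reactive atoms;
* `s = 0.5 w_norm + 0.5 C`, the mode with the highest score wins; exact
  ties go to the more negative eigenvalue (stronger saddle character).

Two conventions here were genuinely open and are worth recording. First,
the score combines `w_norm` rather than the raw eigenvalue — only then are
both summands bounded in [0, 1] and the equal weights meaningful. Second,
mass weighting uses `m` rather than the spectroscopic `sqrt(m)`
convention; the intent of the weighting is to damp hydrogen-dominated
displacement amplitudes, and the stronger damping is retained as the
default. Both the weights and the mass exponent are configuration keys
(`weights`, `mass_power`), so the `sqrt(m)` variant is one argument away.

The winning mode's per-atom contributions `c_i` (squared per-atom norms of
the weighted mode, summing to 1) are compared against
`c_min = min over reactive atoms of c_i`: atoms with
`c_i ≥ threshold_factor · c_min` are *involved*; solvent molecules holding
an involved atom are *active*; involved atoms plus the designated active
atoms are the *relevant* atoms that seed the next, smaller region. The
default `threshold_factor` is 1; 0.85 is the conventional looser variant
for ensemble analyses and is exposed as a parameter.

No rigid-body projection is applied to partial Hessians before scoring: a
frozen environment genuinely breaks translational invariance, so projecting
would discard real information. Projection happens only in the
thermochemistry, on full Hessians.

## Thermochemistry and rates

`species_thermo()` Eckart-projects 3 translations and 3 rotations (2 for
linear species) out of the mass-weighted Hessian, converts eigenvalues to
wavenumbers, discards |ν| < 5 cm⁻¹ as numerical noise (with a warning),
requires exactly one imaginary mode for a transition state and none for a
minimum, and assembles

* U = E_el + U_tra + U_rot + U_vib (translation and rotation each (3/2)RT
  for a nonlinear species; U_vib includes the zero-point energy),
* S = S_tra + S_rot + S_vib (Sackur–Tetrode; rigid rotor with symmetry
  number σ, default 1 since microsolvated clusters are effectively C₁;
  harmonic oscillators),
* H = U + RT (ideal gas), G = H − TS.

For activation quantities between a reactant cluster and its transition
state the translational terms cancel exactly (same atoms) and the pV terms
drop out, leaving ΔH‡ = ΔE_el‡ + ΔU_vib‡ and ΔS‡ = ΔS_rot‡ + ΔS_vib‡; a
test verifies this algebra against the brute-force difference of full G
values. Rates follow Eyring, k = (k_B T/h)·exp(−ΔG‡/RT). CODATA-2018
constants are pinned in one table (`solv_constants`). The default
temperature is 298.15 K and pressure 1 atm; both are ordinary arguments.

Known limitations, by design: harmonic low-frequency modes dominate ΔS_vib
and are the least harmonic in reality; no hindered-rotor or quasi-harmonic
damping is applied; values are per-structure (no conformational
averaging).

## The cavity-entropy correction

A single minimum-energy path starts from an already assembled
solute–solvent cluster, so the entropy penalty of forming that cluster
from its isolated pieces is missing from the standard model. The
correction charges each species the scaled-particle work of carving its
cavity into the continuum:

* packing fraction from the solvent permittivity,
  y = (3/4π)(ε_r−1)/(ε_r+2) — 0 in vacuum, →3/(4π) for a conductor;
* radius ratio R_s = (V_solute/V_solvent)^{1/3} from van-der-Waals
  convex-hull volumes (both volumes must come from the same convention —
  they do, `molecular_volume()` serves solutes and the shipped solvent
  templates alike);
* dimensionless cavity work
  g_c = −ln(1−y) + R_s·3y/(1−y) + R_s²(3y/(1−y) + (9/2)(y/(1−y))²).

The cavity work is read as an energy in units of RT, hence
G_c = RT·g_c and S_c = G_c/T = R·g_c. This reading is a modeling choice
(the expression printed as a bare free energy is not dimensionally an
absolute energy); it reproduces corrections of the expected magnitude —
tens of J/(mol K) — and sign. The temperature derivative of ε_r is
neglected, consistent with defining S_c as G_c/T rather than −∂G_c/∂T.

The activation correction telescopes so that only isolated species enter:
ΔS_c‡ = S_c(TS) − (Σᵢ S_c(R′ᵢ) + n·S_c(L)). For volume-additive clusters
this is provably non-positive — assembling always costs cavity entropy —
and the suite checks the inequality on 1000 random decompositions.
Finally ΔG_c‡ = ΔG‡ − TΔS_c‡.

Shipped solvent parameters are CRC 20 °C permittivities, water 80.10 and
methanol 32.94, pinned so that the 1:1 mole-fraction arithmetic mean is
56.52; mixtures average both ε_r and the molecular volume arithmetically.

## Volumes

`molecular_volume()` samples a deterministic Fibonacci lattice
(`points_per_atom`, default 256, minimum 50) on each atom's van-der-Waals
sphere and takes the volume of the convex hull of the cloud (quickhull,
implemented in the package). The lattice is laid out in a canonical frame
derived from the principal axes of the atom centers (signs fixed by third
moments), so the sampled cloud co-rotates with the structure and the
volume is invariant under rigid motion to solver precision for generic
structures; for nearly point-symmetric structures the frame is ambiguous
and the residual variation is bounded by the lattice discretization
(≈1% at 256 points, shrinking as 1/points). The single-atom hull
underestimates the sphere volume by about 2% at 256 points and converges
from below as the sampling grows; since the cavity model only consumes
volume *ratios* of identically sampled species, this bias largely
cancels.

## The synthetic generators and the toy engine

Because no electronic-structure engine is available (or wanted) in tests,
three generators make every input constructible offline:

* **Microdroplets** — solvent templates placed in two spherical shells
  around the centered reactive complex (volume-uniform radii, random
  quaternion orientations, rejection sampling with a 1.8 Å minimum
  intermolecular separation). Shells default to the complex extent plus
  [2.5, 5.5] and [5.5, 8.5] Å, sized to hold on the order of a hundred
  waters for small solutes; placement is a pure function of the seed.
* **Synthetic TS Hessians** — a unit vector with prescribed
  post-mass-weighting per-atom fractions (amplitudes ∝ √f/m), completed to
  a seeded orthonormal basis, assembled as H = VΛVᵀ with exactly one
  negative eigenvalue. The analysis chain must recover the prescribed
  fractions to 1e-9 and the exact prescribed active-solvent set; this
  round trip is the repository's central parameter-recovery property.
* **Toy engine** — an analytic distance-based potential: harmonic bonds, a
  double-well `h((d−c)²−w²)²/w⁴` on one designated pair (minima at c±w,
  barrier h, and a guaranteed first-order saddle at d = c when all other
  terms are at rest), A/d⁶ intermolecular repulsion and a flat-bottom
  spherical wall that keeps droplets together. Energy, gradient and
  Hessian are closed-form; Hessians are exported in Hartree/Bohr².

The shipped toy reaction is a proton shuttle O–H⋯O with a 0.02 Hartree
(≈52 kJ/mol) double well. Its solvent couples to the complex only through
repulsion, so the decaying mode stays localized on the complex and trials
report zero active solvent molecules — the generator emulates droplet
geometry, frozen-environment bookkeeping and seeded variability, *not*
chemically active solvation. Passing pipeline tests therefore demonstrate
orchestration, determinism, frozen-mask integrity and thermodynamic
consistency on real data-shaped inputs; the active-solvent identification
itself is validated on the synthetic Hessians, where the ground truth is
exact by construction.

## Pipeline and numerical choices

The three stages mirror the staged models: (1) MM relaxation of the
droplet with the complex frozen, fixed-radius large region, two loosened
relaxation passes with region redefinition (convergence thresholds 10×
the base gradient norm of 3e-4 Hartree/Å), a drive of the double-well
coordinate to its barrier top as the stand-in for a single-ended
elementary-step search, and a partial Hessian with the environment
frozen; (2) mode analysis → medium region (s = 2.3) → environment
relaxation → saddle refinement (restrained transverse relaxation
alternating with trust-capped modified Newton steps; near-zero curvatures
are skipped) → downhill walks to both endpoints → disassembly of the
reactant-side cluster into molecules, each optimized in isolation;
(3) mode analysis → small region (s = 2.0) extracted as an isolated
cluster, saddle and reactant refined to 1e-7 Hartree/Å, full-Hessian
thermochemistry, hull volumes (128 points per atom here) and the cavity
correction. Reactant/product labeling uses the double-well distance
(reactant = the shorter donor–proton side). Failed trials are recorded
with stage and cause rather than raised — hit rates are data.

Desk-scale defaults used by the tests and the acceptance script: 8-water
droplets and 204 trials, which one CPU core completes in a few minutes
while exercising every stage boundary. All stochastic inputs are seeded;
a trial is bit-reproducible per seed.

## What the tests do and do not show

Green tests establish: exact agreement of region construction with brute
force; exact recovery of prescribed mode participation; closed-form
agreement of every thermochemical component; the cavity model's limits and
entropy-penalty inequality; and deterministic, internally consistent
three-stage orchestration. They do not establish chemical accuracy of any
real system's barrier — that depends entirely on the electronic-structure
engine plugged in behind the same contracts.
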