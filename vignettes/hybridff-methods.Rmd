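---
title: "Methods: the hybrid-resolution model, its calibration, and the aggregation analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid-resolution model, its calibration, and the aggregation analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridff)
```

This vignette records the modeling assumptions, parameter choices, and
numerical conventions behind `hybridff`, in enough detail that every default
can be audited. Units are GROMACS-style throughout: nm, kJ/mol, ps,
elementary charges, amu; `kB = 0.0083144621` kJ/mol/K and the Coulomb
prefactor `f = 138.935458` kJ mol^-1 nm e^-2.

## 1. The hybrid energy model

A configuration is a `particle_system`: coordinates, a per-particle
resolution tag (`"UA"` united-atom, `"CG"` coarse-grained), type labels for
parameter lookup, charges, masses, chain/residue bookkeeping, an optional
orthorhombic box, and bonded exclusions. The nonbonded energy is a sum over
non-excluded pairs within a cutoff, and it decomposes *exactly* by the
resolution class of each pair:

$$U_\text{total} = U_\text{UA} + U_\text{CG} + U_\text{UA-CG}.$$

This identity is structural (each pair is routed into exactly one class), and
the test suite verifies it to relative error below 1e-9 on random systems.

**Lennard-Jones.** Each pair contributes
$4\epsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6]$, by default
shifted so the energy vanishes at the cutoff (energies are then continuous
across the cutoff; forces are unaffected by the shift). Pair parameters come
from a `pair_table` with symmetric lookup; missing pairs are an error, not a
silent default. `combine_lorentz_berthelot()` provides the geometric-mean /
arithmetic-mean baseline that pair-specific fitting overrides.

**The scaling layer.** Two global factors multiply well depths only:
`eps_cg` (default 0.2) on every CG-CG epsilon and `eps_dual` (default 0.8)
on every UA-CG epsilon. UA-UA terms and all sigma values are untouched. The
defaults reflect the usual situation that unpolarizable CG beads overbind
(so their mutual attraction must be strongly reduced) while cross-resolution
attraction needs a milder correction. Because the scaling is a multiplicative
layer inside the pair sum, $U_\text{CG}$ is exactly linear in `eps_cg` for
uncharged systems — a property the tests exploit. An optional
`scale_coulomb` switch extends the factors to electrostatics; it is off by
default because the calibration this package models rescales Lennard-Jones
well depths and leaves the dielectric model alone.

**Electrostatics.** Cutoff Coulomb with a reaction-field correction:
$U(r) = (f q_1 q_2/\epsilon_r)(1/r + k_{rf} r^2 - c_{rf})$ with
$k_{rf} = 1/(2 r_c^3)$ in the conducting-boundary limit (the default,
`rf_dielectric = Inf`) and $c_{rf}$ fixed so the energy is exactly zero at
the cutoff; beyond the cutoff it is zero by contract. The default cutoff is
1.2 nm. Toy amphiphile systems use a relative dielectric of 15, the common
convention for screened CG electrostatics.

## 2. Toy samplers

The package ships two desk-scale samplers. They exist to generate data whose
ground truth is known, not to simulate production systems.

**Langevin dynamics** uses the BAOAB splitting. With friction and
temperature both zero the update reduces to velocity Verlet, which gives a
clean symplectic-limit test (energy drift < 1e-3 relative over thousands of
steps). With friction on, the integrator reproduces equipartition and the
exact underdamped free-diffusion law
$\mathrm{MSD}(t) = \frac{6 k_B T}{m\gamma}\left(t - \frac{1 - e^{-\gamma t}}{\gamma}\right)$ —
note the ballistic crossover: naive $6Dt$ is wrong by tens of percent on toy
time scales, so the tests compare against the exact expression. Typical
settings: 310 K, friction 1–5 ps^-1, timestep 0.002–0.004 ps.

**Metropolis sampling** (`metropolis_window()`) works directly on the scalar
separation $r$ with target density $\propto e^{-\beta(U(r) + k(r-r_0)^2/2)}$.
Deliberately, *no* $r^2$ Jacobian is included: the sampler targets $U(r)$
itself, matching the default WHAM convention below. Long unbiased runs
Boltzmann-invert to the input potential within 0.2 kJ/mol RMSD.

**Umbrella protocol.** `generate_window_centers()` defaults to 20 evenly
spaced windows spanning 0.25–1.0 nm of pair separation — the standard
protocol for side-chain analog dimers — with a harmonic bias of
1000 kJ/mol/nm^2 by default. The reconstruction tests use 8 windows with
k = 500 kJ/mol/nm^2, chosen so adjacent windows overlap well at 310 K.

## 3. WHAM and first-minimum descriptors

`wham()` bins all window samples on a common grid (default 0.01 nm) and
iterates the standard self-consistent equations until the largest change in
any window offset falls below `tol` (1e-7 kJ/mol). Non-overlapping window
chains are rejected up front with the offending pair of centers named, since
WHAM silently produces garbage across sampling gaps.

Two conventions deserve emphasis:

* **Jacobian.** By default no radial-entropy correction is applied: the
  profile estimates whatever effective 1-D potential generated the samples,
  which is correct for the scalar Metropolis sampler. For samples of an
  isotropic 3-D separation vector (the Langevin umbrella route),
  `jacobian = TRUE` adds $+2 k_B T \ln r$. The test suite cross-validates
  the two routes against each other on the same pair potential and verifies
  that the flag changes the profile by exactly $2 k_B T \ln r$ plus a
  constant.
* **Zero.** `"zero-at-rmax"` (default) anchors the profile at the largest
  well-sampled separation, the natural convention when well depth is
  measured against the dissociated plateau; `"min-is-zero"` is also
  available. Depth comparisons in tests always re-align profiles before
  differencing, so the convention never leaks into results.

`first_minimum()` scans populated bins from small $r$ for the first discrete
local minimum (optionally after a moving-average smooth), then refines the
position by a parabola through the minimum bin and its neighbors — sub-bin
accuracy on analytic profiles (position error < one 0.01 nm bin, depth error
< 5%). Monotone profiles return a distinguished "no minimum" result rather
than an arbitrary number; downstream code treats that case explicitly
(`fit_cross_lj()` penalizes it heavily instead of aborting).

## 4. Two-stage calibration

**Stage one** (`fit_cross_lj()`) fits $(\epsilon, \sigma)$ of a cross pair by
Nelder–Mead on the objective
$w_d\,|\Delta \text{depth}| + w_p\,|\Delta \text{position}|$ between the
first minima of candidate and reference profiles, with parameters clipped to
bounds. The default weights ($w_d = 1$ per kJ/mol, $w_p = 10$ per nm) make a
0.1 nm position miss cost as much as a 1 kJ/mol depth miss, reflecting that
position errors distort packing more than depth errors of the same nominal
size. Against analytic reference profiles the fit recovers planted
parameters within 5% in epsilon and 0.01 nm in sigma in at least 9 of 10
random draws.

**Stage two** (`calibrate_scaling_factor()`) scans a coarse candidate grid
(default 0.1–1.0 in steps of 0.1, matching the granularity at which such
factors are reported), generates a radius-of-gyration ensemble per candidate,
and selects the candidate minimizing a distribution distance to the
reference. The default metric is the 1-D Wasserstein distance — robust to
binning, and exactly $|\delta|$ for a pure location shift. Ties break toward
the smaller candidate so the result is independent of candidate order. The
desk-scale ensemble generator is `polymer_rg_ensemble()`: a 10-bead chain
with harmonic bonds (k = 500 kJ/mol/nm^2, b = 0.47 nm) and scaled
Lennard-Jones attraction, sampled by single-bead Metropolis moves plus one
pivot move per sweep for decorrelation. Mean Rg decreases monotonically with
the scaling factor over the default grid, and the scan recovers a planted
factor of 0.2 from an independently seeded reference.

## 5. Aggregation analyses

**Clustering** (`find_clusters()`) is single-linkage on chains: chains link
when any inter-chain particle distance falls strictly below the cutoff
(default 0.6 nm), and clusters are connected components. The partition is
transitive, invariant under relabeling, and can only coarsen as the cutoff
grows; it is tested against an independent union-find implementation.

**Growth kinetics** (`fit_growth_exponent()`) fits
$\ln n = \alpha \ln t + c$ by OLS. Exponents near 1 indicate
diffusion-limited coagulation, much smaller values (~0.25) a
reaction-limited regime. Noiseless power laws are recovered exactly; under
multiplicative log-normal noise the estimate is unbiased with an honest
standard error.

**Encounters** (`encounter_events()`, `com_distance_series()`) are maximal
intervals during which the inter-cluster center-of-mass distance stays below
a threshold (3 nm by default); fusion frames are flagged when any
inter-group particle contact falls below the cluster cutoff. Cluster centers
of mass unwrap about an anchor particle via minimum image, valid while a
cluster's extent is below half the box edge — the only regime where a
cluster COM means anything.

**Beta structure** is assigned from geometry alone (one backbone site per
residue), since hydrogen-bond-based assignment is undefined for
mixed-resolution chains. A residue is *extended* when its two sequence
neighbors' backbone sites are more than 0.64 nm apart (terminal residues
inherit their neighbor's flag); an extended run of at least 3 residues
becomes a strand only when each residue has a cross-chain backbone partner
at 0.42–0.58 nm, bracketing the canonical ~0.48 nm sheet spacing. Registry
classification (`classify_registry()`) orients a strand pair by the sign of
the dot product of their direction vectors (|cos| < 0.3 is "other"), maps
each core residue (positions 1–4, the amyloidogenic L-V-F-F stretch of the
fixture peptide) to its nearest cross-strand site, and requires an *exact*
match to the in-register parallel template (1-1 … 4-4) or antiparallel
template (1-4, 2-3, 3-2, 4-1). `amyloid_fractions()` pools pair labels and
residue counts into beta / amyloid / parallel / antiparallel fractions.

## 6. Fixtures: what the generators emulate

Every test input is generated in code, deterministically per seed:

* `enumerate_analog_pairs()` — the 12 side-chain analogs (one per CG
  side-chain bead chemistry class) give 144 *ordered* dimers, first member
  UA and second CG, in a 3 x 4 x 3 nm box: the systems a cross-term
  parameterization campaign would sweep.
* `build_beta_sheet()` — ideal strands at 0.35 nm intra-strand and 0.48 nm
  inter-strand spacing, in parallel, antiparallel, or register-shifted
  arrangements with known ground-truth labels. In the antiparallel layout
  alternate strands are reversed so the four core residues pair exactly
  reversed; the overhanging fifth residue then has no aligned partner, which
  the strand detector faithfully reports.
* `build_micelle_toy()` / `relax_micelle_toy()` — two-bead amphiphiles
  (sticky UA tail, charged CG head, harmonic bond) that condense under
  Langevin dynamics into a core-corona arrangement. The ordering statistic
  (mean head distance minus mean tail distance from the assembly center) is
  computed inside the largest tail cluster, because a global center of mass
  is meaningless while several small clusters coexist. Bonds are placed
  symmetrically about their midpoint at setup so that neither bead class
  starts biased outward — an earlier asymmetric placement produced spurious
  "ordering" in uncharged controls.
* `synth_growth_series()` — $n(t) = t^\alpha e^\eta$ with i.i.d. Gaussian
  log-noise, for exercising the exponent fitter.
* `make_double_well()` — a quartic two-minimum radial potential with a steep
  short-range wall, the planted ground truth for WHAM reconstruction.

## 7. Numerical choices and limitations

* Problem sizes (tens of particles, 10^4–10^5 Monte Carlo samples, 10-bead
  polymers) are chosen so the full test suite runs in minutes while leaving
  clear statistical margins; they are this package's choice, not a claim
  about production workloads.
* All stochastic functions take explicit seeds and are exactly reproducible;
  identical CLI invocations give byte-identical outputs.
* The energy model is nonbonded-only; bonded terms enter the toy samplers
  as explicit extra forces (`harmonic_bond_force()`), not the pair table.
* Minimum-image is correct for orthorhombic boxes and interactions shorter
  than half the box edge; the tests verify agreement with explicit 27-image
  enumeration in that regime.
* The WHAM implementation is the plain self-consistent iteration; for the
  window counts used here it converges in well under 10^5 iterations, and
  non-convergence is an error, never a silent partial result.
* Registry classification requires an exact template match over the core
  residues, so near-registry arrangements (off by one residue) are labeled
  "other" rather than fractionally amyloid — a deliberate, conservative
  convention.
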