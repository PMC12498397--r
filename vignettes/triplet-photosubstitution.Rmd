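---
title: "Modelling ligand photosubstitution on the triplet hypersurface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligand photosubstitution on the triplet hypersurface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(photosub)
```

## The problem

Ruthenium polypyridyl complexes carrying a photolabile thioether ligand are
candidate prodrugs for photoactivated chemotherapy: green or red light
promotes the complex into a triplet metal-to-ligand charge-transfer state
(³MLCT), from which the Ru–S bond can break and a water molecule can
coordinate, releasing the thioether. The efficiency of this photosubstitution
varies by an order of magnitude across closely related complexes, and static
gas-phase electronic-structure metrics (the ³MLCT→³MC energy gap or its
transition-state barrier) fail to predict it.

`photosub` implements the dynamical analysis layer for this problem. Two
collective variables (CVs) summarise the reaction: the Ru–S distance of the
breaking bond and the minimum Ru–O distance over all water oxygens
(`d_RuOmin`), the forming bond. On this plane the package

* samples analytic model surfaces under the combined enhanced-sampling
  protocol (umbrella windows along Ru–S, well-tempered metadynamics along
  Ru–O_min),
* reconstructs the two-dimensional free-energy surface (FES) with WHAM,
* splits configurations into *cis* (S–Ru–O_min ≤ 90°) and *trans*
  (> 90°) attack geometries,
* classifies the ligand-exchange mechanism (dissociative / interchange
  variants / associative / photoinactive) from the intermediates along the
  minimum-energy path, and
* computes the chelate planarity–rigidity descriptors and the
  correlation/regression statistics that link molecular structure to the
  measured photosubstitution quantum yields.

The QM/MM engine that produced the original trajectories is out of scope:
the simulator here evolves the CVs directly on analytic model potentials
whose exact free energy is known, so every estimator can be validated against
ground truth.

## Model potentials and what they emulate

Six archetype surfaces (`archetype_potential()`) realise the mechanistic
taxonomy. Each is a reaction valley — a Gaussian channel of depth 8 kJ/mol
along a waypoint polyline — with Gaussian station basins at the chemically
meaningful locations: an MLCT basin at (2.55, 4.5) Å where photon absorption
deposits the system, optional MC / pentacoordinate / heptacoordinate
intermediates, and an aqua-product basin. Basin depths (4–7 kJ/mol below the
channel floor) are on the scale of the computed triplet barriers for this
compound family (roughly 1–15 kJ/mol). The photoinactive archetype is a
single MLCT basin on a monotonically rising landscape. The associative
archetype carries an explicit transition-state pinch between the MLCT basin
and the heptacoordinate intermediate so the two basins remain resolvable at
sampling noise; its intermediate sits at Ru–O_min 3.5 Å, safely inside the
4.0 Å interaction cutoff (the classifier's boundary behaviour at 3.75 Å is
unit-tested on a constructed grid instead).

What the generator deliberately does not emulate: explicit water, chemical
detail of the chelate, coupling between the dihedral and the reaction
coordinates (the dihedral process is independent by default), or
intersystem crossing. A passing suite therefore demonstrates that the
estimators and classifiers are correct on surfaces with known answers, not
that any particular real complex follows a given mechanism.

## The sampling engine

`simulate_langevin()` is a BAOAB-splitting Langevin integrator acting
directly on the CVs with a fictitious mass of 1 amu, a 0.002 ps timestep and
T = 300 K. The friction is per-coordinate, default `c(20, 1.5)` ps⁻¹: the
umbrella-restrained Ru–S coordinate is damped near-critically so successive
samples decorrelate quickly (the window force constant of 350 kJ/mol/Å²
gives an oscillation frequency of ~19 rad/ps), while the metadynamics
coordinate is kept diffusive enough (D = kT/γm ≈ 1.7 Ų/ps) to traverse its
4 Å range many times per 40 ps window. These are sampling-efficiency choices
of the toy engine; no thermostat constant of the original QM/MM protocol
maps onto them.

The protocol parameters themselves are fixed at their published values and
are the package defaults everywhere: 20 umbrella windows from 2.50 Å in
0.15 Å steps (last centre 5.35 Å), k = 350 kJ/mol/Å², 5 ps equilibration and
40 ps production per window; metadynamics hills of initial height 2.0
kJ/mol, width 0.1 Å, pace 50 steps, bias factor γ = 15.

Two engine-level additions stabilise the toy protocol:

* **Restraining walls** on the metadynamics CV (half-harmonic, default
  [2.05, 5.95] Å, 1000 kJ/mol/Å²) keep hills and samples on the analysis
  range; the wall energy is part of the bias and is removed exactly during
  reweighting.
* **Hill persistence across windows** is the default
  (`persist_hills = TRUE`). With per-window resets, every window re-fills
  the Ru–O wells from scratch, and during that filling transient the sampled
  distribution lags the rapidly growing bias; the reconstructed intermediate
  basins were visibly displaced or erased. With a persistent bias the
  landscape is essentially flattened after the first windows and later
  windows sample close to equilibrium. The per-window reset variant remains
  available.
* **Multiple walkers** (`n_walkers`): independent replicas of the whole
  schedule, pooled in WHAM. The analyses in the test-suite and acceptance
  script use two walkers.

## Free-energy reconstruction

`wham_2d()` removes the bias in two layers. Each window's production is cut
into 10 time segments; within a segment the well-tempered bias is frozen at
its segment-midpoint form (quasi-static approximation — tempered hills
shrink, and freezing at the midpoint centres the within-segment growth
error). Each (window, segment) pair enters binned WHAM as one biased state
whose bias — umbrella + frozen metadynamics + walls — is evaluated at the
bin centres; every sample additionally carries a within-bin correction
weight `exp(β (V(sample) − V(bin centre)))`, without which the steep
restraints (several kJ/mol of variation across one 0.067 Å bin) corrupt the
binned estimator. The state free energies are iterated to self-consistency
(tolerance 10⁻⁶ kJ/mol on max |Δf|, gauge f₁ = 0).

The default grid is 60 × 60 bins over [2, 6] Å × [2, 6] Å with a sampled
mask at ≥ 5 raw samples per bin. Bins whose Ru–S coordinate lies more than
one window spacing outside the span of window centres are additionally
masked: umbrella windows only inform their restrained neighbourhood, and
estimates in the exponential tails rest on a handful of heavily reweighted
samples (unmasked, those fringe bins showed errors of 5–14 kJ/mol while the
interior is accurate to a fraction of kT). The mask rule is part of the
output metadata.

At protocol scale with two walkers, the reconstruction error over sampled
bins (after removing the free additive constant) is 0.55–0.67 kT across all
six archetypes — the acceptance suite requires ≤ 1 kT.

## Mechanism classification

`classify_mechanism()` works on the dominant pathway's FES:

1. The photon-absorption region is an axis-aligned ellipse at the per-CV
   means of an unbiased run, semi-axes 1.96 σ per CV. The per-axis
   convention follows from computing per-CV standard deviations, not a
   covariance ellipse; its joint coverage for Gaussian CVs is ≈ 0.85, and
   the coverage test asserts the convention's own analytic value. In the toy
   setting the "singlet ground state" is modelled as a harmonic basin at the
   MLCT geometry, since only the unbiased spread matters.
2. The surface is smoothed (mask-aware Gaussian kernel, 1.5 bins) and minima
   with escape depth ≥ 1 kT (2.5 kJ/mol) whose 8-neighbourhood is fully
   sampled are retained; shallower or mask-boundary basins are statistical
   texture at this sampling scale.
3. The minimum-energy path (MEP) runs from the absorption region to the
   lowest product bin (Ru–S > 4 Å, Ru–O_min ≤ 2.5 Å) under the minimax
   criterion (8-connected path minimising the maximum F, ties broken by the
   lower integrated F).
4. Only reactive minima — MC, pentacoordinate, heptacoordinate or product,
   spin-gated when a spin field is available — lying within 0.25 Å of the
   MEP define the verdict: pentacoordinate ⇒ dissociative; heptacoordinate ⇒
   associative, downgraded to interchange-associative when its Ru–O_min is
   strictly within 0.25 Å of the 4.0 Å cutoff (so an intermediate at exactly
   3.75 Å is associative, and flagged borderline); otherwise the crossing
   order of the two coordinates along the MEP decides the interchange
   subtype, with a flat path (barrier < 1 kT) left as plain interchange. If
   no reactive minimum exists beyond the MLCT region, the verdict is
   photoinactive.

The spin surrogate maps the CV pair to a Ru Mulliken-spin value anchored at
~0.7 for the bound MLCT geometry, > 1.2 once the thioether has left with no
water bound (³MC), relaxing to ~0.8 when the aqua ligand coordinates (³P).

## Descriptors and statistics

The chelate dihedral θ between the Ru–N_C–C_C and Ru–N_T–C_T half-planes is
signed by a fixed orientation convention; folding onto [0, 90]°
(`fold_theta()`, 90 − |90 − (|θ| mod 180)|) erases the bending direction.
Planarity μ(θ) is the mean of the folded angle, rigidity σ(θ) its
population (1/n) standard deviation. The generator's θ process is an exact
Ornstein–Uhlenbeck discretisation; with means in the 15–69° range and
spreads of a few degrees the folding bias is negligible and both parameters
are recovered within 2% / 10% at 20,000 frames.

`spearman_rank()` computes ρ as the Pearson correlation of midranks; the
two-sided p-value is exact (full permutation enumeration, evaluated in
memory-bounded chunks) up to n = 10 and a t-approximation beyond — the
upstream analysis does not state its p-value method, so the exact choice is
conservative at the table sizes involved. `linear_fit_ci()` is ordinary
least squares with the confidence band half-width
`t_crit · s · sqrt(1/n + (x* − x̄)²/Sxx)`. The photoinactive complex enters
all rank and regression analyses with quantum yield 0 (its cell in the
measured table is empty); this zero-assignment convention is the one under
which the packaged tables reproduce the published ρ = −0.40 / −0.43 and
R² = 0.01 against both barrier variables, and it is applied by
`compound_tables()` by default.

## Numerical choices and degenerate inputs

* Boltzmann constant 0.0083144626 kJ/mol/K; all energies kJ/mol, distances
  Å, times ps.
* Metadynamics force in the engine is linearly interpolated from a fine
  (0.01 Å) incremental grid cache of the hill sum; the exactly summed form
  remains the reference in `bias_energy()` and the tests.
* An attack angle of exactly 90° counts as *cis* (documented tie rule);
  zero qualifying samples yield an explicit empty statistics object, never
  0/0.
* Frames with either Ru–N distance beyond 4 Å are flagged monodentate-like
  but never dropped; collinear plane atoms raise an undefined-plane error.
* A constant descriptor vector makes ρ undefined and is rejected, as is a
  constant abscissa in the regression.
* Problem sizes in the shipped tests: 2 walkers × 20 windows × 40 ps per
  archetype for the reconstruction checks; 3 × 10⁵-step runs for the
  equipartition, diffusion and well-tempered-limit checks; 20,000 frames for
  descriptor recovery; 10,000 draws for attack statistics.

## Known limitations

* The quasi-static segment treatment leaves residual local errors of order
  1 kT where the bias is still actively filling; deep, narrow basins closer
  than ~1 Å to a much deeper neighbour can merge at this sampling scale.
* The minimax MEP is a watershed path, not a steepest-descent string; on
  broad flat channels its geometric course between the bottlenecks is only
  loosely constrained (its maximum is what the classifier uses).
* The classifier's verdicts inherit the 4.0 Å cutoff and 0.25 Å margin
  conventions; surfaces whose intermediates sit exactly at these boundaries
  are reported as borderline rather than silently resolved.
* Attack angles and the chelate dihedral are generated independently of the
  reaction coordinates in the synthetic pipeline; real trajectories couple
  them.
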