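---
title: "Methods: MM-PBSA scoring and pharmacophore screening for XIAP-BIR3 ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MM-PBSA scoring and pharmacophore screening for XIAP-BIR3 ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(xbir3)
```

## The problem

XIAP (X-linked inhibitor of apoptosis protein) suppresses apoptosis by
binding caspase-9 through the surface groove of its BIR3 domain
(residues 248–352 in the crystallographic constructs).  Small-molecule
antagonists of that groove — "Smac-mimetics" and later fully synthetic
ligands — are candidate anticancer agents, and their rational optimisation
needs two desk-scale tools: a way to *rank* candidate ligands by binding
free energy from conformational ensembles, and a way to *screen* large
chemical libraries with a 3D pharmacophore distilled from the complexes.
`xbir3` implements both ends of that workflow, together with the
trajectory quality-control analyses that sit between them and seeded
synthetic-data generators that make every stage testable without running
molecular dynamics or downloading external libraries.

## The binding free-energy model

The end-point estimate is standard MM-PBSA over an ensemble of complex
snapshots:

$$\Delta G = \langle E_{inte} + G_{polar} + G_{non\text{-}polar} \rangle - T\Delta S$$

with the single-trajectory approximation throughout: the free receptor and
free ligand are obtained from each complex frame by deleting the other
segment's atoms (`split_complex()`), so intramolecular terms cancel in the
difference and are never computed.

* **Interaction energy** $E_{inte}$: exact Coulomb + Lennard-Jones pair
  sums between receptor and ligand atoms, vacuum dielectric
  ($\varepsilon = 1$), Coulomb constant 332.0636 kcal·Å/(mol·e²), CHARMM
  combining rules ($\varepsilon_{ij} = \sqrt{\varepsilon_i\varepsilon_j}$,
  $r_{min,ij} = r_{min,i}/2 + r_{min,j}/2$).  No cutoff is applied: cutoffs
  and switching belong to the MD engine that generated the ensemble, not to
  post-processing, and exact sums are cheap at desk scale.
* **Polar solvation** $G_{polar}$: finite-difference linearized
  Poisson–Boltzmann.  Three solves (complex, receptor, ligand) on an
  identical grid spec, each as a *two-solve difference* — solvent
  dielectric with Debye screening minus a uniform-`eps_in` reference on the
  same grid — so the grid self-energy cancels exactly.
* **Non-polar solvation**: the linear SASA model
  $0.00542 \times \mathrm{SASA} + 0.92$ (kcal/mol, Å²), evaluated per
  species and differenced.  Whether the 0.92 intercept applies per species
  or once per binding event is not specified by the source protocol; this
  package applies it **per species** (the literal reading of the
  three-term difference), which contributes a constant −0.92 kcal/mol to
  every $\Delta G_{non\text{-}polar}$.  The convention is recorded in the
  output (`intercept_convention` column) so results are unambiguous.

The reported spread is the population standard deviation (divide by *n*)
of per-frame totals, matching the usual "mean ± SD" convention of MM-PBSA
tables; the convention is stored in the estimate (`sd_convention`).  The
entropy term is a single ensemble-level quantity added to the mean, not a
per-frame term.

### The PB solver

The solver (C++ core, red–black successive over-relaxation) discretizes
$\nabla\!\cdot\!(\varepsilon\nabla\phi) - \bar\kappa^2\phi = -4\pi C\rho$
on a uniform grid:

| parameter | default | notes |
|---|---|---|
| `eps_in` | 1 | vacuum solute dielectric, matching the scoring convention |
| `eps_out` | 80 | water |
| `ionic_strength` | 0.15 M | 1:1 salt; Debye length ≈ 7.9 Å |
| `spacing` | 0.5 Å (0.8 Å in ensemble loops) | must be ≤ 1 Å |
| `padding` | 10 Å | minimum 8 Å |
| `tol` | 1e-6 | relative residual, L2, normalized by the source norm |

Numerical choices that matter:

* charges are spread to the eight surrounding nodes with trilinear
  weights; potentials are read back at atom centres with the same stencil;
* the dielectric boundary is the van der Waals surface from `pb_radius`
  (no probe smoothing), and each inter-node edge carries the **harmonic
  mean** of the dielectric along it, weighted by the exact fraction of the
  edge inside the solute.  This fractional-fill assignment is what makes
  the Born-ion validation converge: the solver reproduces the Born closed
  form to 0.3% at 0.4 Å spacing and ~2% at 0.8 Å (the acceptance
  tolerances are 2% and 5%);
* Dirichlet boundary values come from the single-sphere Debye–Hückel
  superposition; the SOR relaxation factor is
  $2/(1+\sin(\pi/\max(\mathrm{dims})))$;
* the ionic screening term is applied at solvent nodes only (no Stern
  layer — a documented simplification).

SASA uses deterministic golden-spiral quadrature (default 480 points per
atom, 240 in ensemble loops; the error floor check refuses fewer than 24)
over heavy atoms with a 1.4 Å probe.  Accuracy against the closed
isolated-sphere and two-sphere-cap forms is ~0.5% at the defaults.

## Entropy estimators

**Interaction entropy (IE)** evaluates
$-T\Delta S = k_BT\,\ln\langle e^{\Delta E_{inte}/k_BT}\rangle$ over the
centred interaction-energy series, with $k_BT$ taken per mole (RT,
R = 1.9858775 × 10⁻³ kcal/K/mol) because every energy in the pipeline is
molar.  The exponential average is computed by log-sum-exp, so it cannot
overflow; it is non-negative for any series (Jensen) and exactly zero only
for a constant series.  For Gaussian fluctuations the estimator converges
to $\sigma^2/2RT$; the known practical hazard is the exponential variance
blow-up for large $\sigma$, so a diagnostic warning fires when
$\sigma > 3RT$ rather than truncating the average silently.

**Normal-mode (NM) entropy** minimizes a caller-supplied energy function
(the bundled `harmonic_ff()` provides bonds + angles with the ½k
convention, so a diatomic with bond constant *k* vibrates at
$\sqrt{k/\mu}$) to gradient RMS ≤ 1e-5 kcal/mol/Å, builds the
mass-weighted Hessian by central finite differences (step 1e-4 Å),
removes the 6 external modes (5 for linear species; the count is
auto-detected from the near-zero spectrum and overridable), errors on any
remaining imaginary frequency, and accumulates the quantum
harmonic-oscillator entropy per retained mode.  NM on full protein force
fields is deliberately out of scope; the pluggable energy function is the
supported route.

## Trajectory analyses

Superposition is the Kabsch SVD solution with the determinant correction
(always a proper rotation).  Core-backbone RMSD uses residues 259–335 when
present — the BIR3 core between the flexible N-terminus (248–258) and
C-terminus (336–352) — falling back to all receptor residues for toy
systems; the reference is the first frame unless an external reference is
supplied.  Ligand RMSD applies the core superposition to the ligand and
flags mean values above 2 Å as unstable binding.

Hydrogen bonds use a 3.5 Å donor–acceptor distance and, only when a
hydrogen is given, a 120° D–H⋯A angle.  Neither criterion is dictated by
the source protocol; these are common practice, are config-overridable,
and every report records them.  Contact maps count any-heavy-atom contacts
at a 4.0 Å default cutoff.

## Pharmacophore construction and screening

Feature perception is a deliberately simple rule set (the proprietary
perception of commercial tools is out of scope and is **not** emulated):
HBD at donor heavy atoms, HBA at acceptors, hydrophobic (H) at centroids
of connected clusters of ≥ 3 non-ring carbons, aromatic-hydrophobic (HAr)
at flagged ring centroids.  A ligand feature is retained only when its
receptor partner condition holds (complementary donor/acceptor within
3.5 Å; any receptor heavy atom within 4.0 Å for H/HAr); over an ensemble
the condition must hold in ≥ 50% of frames (threshold tunable) and the
feature centre is the frame-average position.  Exclusion volumes (radius
1.0 Å) sit on receptor heavy atoms within 6 Å of the ligand.  Default
feature tolerance is 1.5 Å.  Merging fuses same-kind features within
1.5 Å to their midpoint and unions the rest.

Matching is deterministic exhaustive assignment: for each allowed omission
set (none, or each single feature), every kind-respecting injective
assignment of model features to entry feature points is enumerated
(internal-distance pruning first, then Kabsch superposition on the
assigned centres), and an entry matches when every assigned pair falls
within its tolerance and no heavy atom enters an exclusion volume.  This
is a deterministic superset of "randomly discard one feature": where the
commercial tool might or might not find the permissive omission, the
enumeration always does.  The combinatorial guard errors beyond 10⁶
assignments per entry.

Screening metrics follow the standard definitions — sensitivity TP/A,
specificity TN/I, enrichment factor $(TP/H_{tot})/(A/D)$ with **D the full
labelled dataset size** A + I = 5590 for the validation composition (this
choice reproduces the published EF values, e.g. 32.3 and 20.4, whereas
the post-exclusion count 5494 does not).  Full ROC AUC uses the
Mann–Whitney pair-counting equivalence with ties counted ½; the "early"
AUC at a top fraction (default 1.5%) is the partial ROC area over the
covered false-positive range with McClish standardization (random = 0.5,
perfect = 1).  The early-AUC definition is not published for the reference
screen; this documented convention is flagged in output.

## What the synthetic generators emulate — and what they do not

The generators define the study conditions for all tests:

* **Toy complexes**: arc-shaped 4-atom-per-residue receptor chains with
  CHARMM-like partial charges and a grouped multi-atom ligand (tags
  G1…Gk).  They exercise every bookkeeping path (selections, splits,
  decompositions) but are not force-field-quality geometries.
* **Ensembles**: i.i.d. Gaussian coordinate jitter (default σ = 0.3 Å,
  roughly the core-backbone fluctuation scale of a stable complex) plus
  *planted* hydrogen-bond schedules: scheduled acceptor atoms are placed
  at 2.9 Å (bonded frames) or 6.0 Å (unbonded) from their donor along the
  base direction, with the bonded frame set chosen by a seeded shuffle —
  occupancy is exact by construction, not by sampling.  The planted 87.4%
  pattern over 2500 frames mirrors the occupancy scale reported for the
  key Glu314 salt bridge.  What is *not* emulated: correlated motions,
  anisotropic fluctuations, conformational transitions, or the dynamical
  effects of hydrogen-mass repartitioning and cation-π parametrizations
  (ensembles carry a free-text provenance tag instead).
* **Screening libraries**: the validation composition (173 actives, 5417
  inactives; actives pIC50 ∈ (6, 9], decoys ∈ [3, 4.5), the 4.5–6 band
  generated only on request and flagged "excluded").  Actives reproduce
  the reference model geometry up to clamped jitter (σ = 0.3 Å, hard-capped
  at 0.45× the smallest tolerance, so a clean active can never fail);
  decoys have ≥ 1 feature (default 2) moved radially *outside* the whole
  feature cloud, so no assignment can rescue them — the planted confusion
  matrix is exact.  Decoys are feature-violating placements only; no
  property matching of physicochemical descriptors is attempted, so
  passing screens say nothing about decoy realism on real libraries.

Because the planted truths are exact, test passes demonstrate that the
analysis operations *recover what was planted*; they do not demonstrate
predictive accuracy on real MD ensembles or real chemical libraries,
which would require the original trajectories and the external library.

## Reference tables bundled with the package

`xiap_affinity_table()` carries the five complexes (5C7C, 5M6M, 5OQW,
5M6L, and the docked AVPI peptide), their IC50 values and the published
MM-PBSA predictions from HMR-parametrized trajectories; these are the
inputs to the correlation benchmark (r = 0.983 without entropy, 0.975
with the IE term, over the four synthetic-ligand complexes — AVPI is
excluded by default as a peptide reference and because its tabulated
ΔG_exp (−8.91) disagrees with the IC50 conversion (−9.00); the benchmark
flags the discrepancy rather than resolving it).
`xiap_screening_counts()` carries the published TP/TN counts of the five
pharmacophore variants for count-replay of the evaluation metrics.  One
further published inconsistency is surfaced rather than hidden: the n°5
row prints 78.1% sensitivity alongside TP = 136, but 136/173 = 78.6%, and
the metrics operation returns the value implied by the counts.

## Problem sizes and budgets

The test suite runs toy complexes of 3–30 residues, ensembles of up to
2500 frames for occupancy recovery (analysis-only) and 2–10 frames where
every frame needs PB solves, PB grids at 0.4–1.0 Å spacing, an IE series of
10⁶ samples, and screening libraries of 15–120 entries (the acceptance
script screens the full 5590-entry composition once, at zero omissions).
These sizes were chosen so each check exercises its numerical regime —
grid convergence, exponential-average convergence, assignment
combinatorics — while the whole suite stays comfortably interactive.

## Known limitations

* Linearized PB only; no nonlinear Boltzmann term, no GB fallback, no
  periodicity, no Stern layer, no probe-smoothed dielectric boundary.
* The per-residue polar attribution (½·qᵢ·Δφ_rf(rᵢ), summed per residue;
  receptor *and* ligand rows so the attribution sums to ΔG_polar exactly)
  is the standard charge–potential scheme, but like all such schemes it is
  a convention, not an observable; the SASA intercept is kept out of the
  rows as a separate offset so row sums stay meaningful.
* Pharmacophore perception is rule-based on typed atoms; it does not
  perceive protonation states, tautomers, or ring aromaticity from
  connectivity, and HAr is a point feature without a plane-normal
  constraint.
* Absolute ΔG_MM-PBSA values of the real complexes are not reproducible
  here — they require the original 50-ns trajectories — so the benchmark
  operates on the published prediction tables and on planted synthetic
  conditions.
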