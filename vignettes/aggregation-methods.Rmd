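---
title: "Methods: stacking census and the aggregation-corrected K_OA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacking census and the aggregation-corrected K_OA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaggr)
```

# The problem

Aromatic pollutants dissolved in *n*-octanol associate through π–π stacking
into dimers, trimers and occasionally larger aggregates. Because aggregates
are effectively absent from the gas phase, their presence in the octanol
phase raises the *apparent* octanol–air partition coefficient K_OA above
the monomer-only value, and the effect grows with concentration. `octaggr`
implements the analysis chain that quantifies this: composition arithmetic,
stacked-contact detection on periodic-box trajectories, an aggregate
census, and the corrected apparent log K_OA.

# Composition arithmetic

The apparent saturated octanol solubility follows from the equilibrium
relation K_OW = S_O/S_W, i.e. `S_O = s_w * 10^log_kow`. Converting a molar
concentration into a box composition requires the molarity of the solvent;
the package uses **6.344 mol/L** for pure *n*-octanol (density
0.8262 g/cm³ over 130.23 g/mol) with nearest-integer (half-up) rounding of
the solute count. This constant is exposed as `octanol_molarity` in
`molecule_count()`; with it, every reference box composition — 24, 35, 24,
15 and 34 solutes per 1000 octanol molecules, and 61 per 4000 at
9.67 × 10⁻² mol/L — is reproduced exactly, which is why it was adopted.
Dilution assumes the solute does not change the solvent volume (ideal
dilution); no activity-coefficient corrections are applied.

Displayed concentrations round half-up to 3 decimals (mol/L), percentages
to 1 decimal, and averaged experimental log K_OA values to 2 decimals. All
internal arithmetic keeps full precision; rounding is applied only at the
reporting boundary. Half-up (away-from-zero) rounding is used throughout
rather than R's round-to-even, because the reference tables were printed
with that convention (e.g. 14/34 → 41.2).

# Trajectory model

Trajectories are orthorhombic periodic boxes with per-frame coordinates in
Å and an explicit molecule grouping (atom index blocks for XYZ, residues
for GRO/PDB, or fully explicit), including per-molecule aromatic ring
lists. Grouping is deliberately explicit rather than inferred by bond
perception: it keeps the core free of a chemistry-perception dependency
and lets solvent be excluded by listing only solute residues. GRO files
are converted from nm at the boundary and may carry velocities, which are
parsed and discarded; triclinic boxes are rejected with a clear error.
Distances always use the minimum-image convention, wrapping each Cartesian
component into [−L/2, L/2).

Molecule centroids unwrap the molecule first (all atoms shifted to the
periodic image nearest the first atom), so molecules split across the box
boundary are handled correctly. The geometric (unweighted) centroid is the
default; mass weighting is available but changes little for the roughly
symmetric solutes this package targets.

# Stacked-contact detection

A pair is a stacked contact when its centroid distance falls below a
conformer-specific cutoff:

| conformer            | cutoff | geometric condition                          |
|----------------------|--------|----------------------------------------------|
| face-to-face         | 3.8 Å  | interplanar angle γ ≤ 50°, lateral slip < 1.0 Å |
| offset face-to-face  | 3.9 Å  | γ ≤ 50°, larger slip                         |
| edge-to-face         | 5.0 Å  | γ > 50°                                      |

The three distance cutoffs are the established recognition thresholds for
these stacking motifs. The angular subdivision is this package's
reconstruction: only the distances are standard, so the parallel/T-shaped
split at γ = 50° and the eclipsed/offset split at 1.0 Å lateral slip follow
the stacking-geometry literature conventions, and both thresholds are
exposed in `stacking_criteria()`. γ is the angle between best-fit ring-plane
normals folded to [0°, 90°] (normals are sign-free); the lateral slip is
the component of the centroid separation perpendicular to the mean normal.

Classification is a cascade — face-to-face is tested first, then offset
face-to-face for any parallel pair within 3.9 Å, then edge-to-face — so the
most specific conformer wins when a geometry satisfies more than one
cutoff. One consequence: a parallel pair with zero slip at 3.85 Å
classifies as offset face-to-face (it fails the 3.8 Å eclipsed cutoff but
is within 3.9 Å); since the census only needs contact/no-contact, this
affects labels, not cluster counts.

Two distance modes exist. `molecule-centroid` (default, and the literal
reading of the recognition rule) tests whole-molecule centroids with each
molecule's best-fit plane over all its ring atoms. `ring-pair` tests every
ring pair and lets the closest qualifying pair decide — more defensible for
large multi-ring solutes whose molecular centroid sits between rings, but
not the default because the reference analysis is defined on molecule
centroids.

Aggregates are the connected components (via `igraph`) of the undirected
contact graph; singletons are monomers. The census reports
100·k·n_k/N for k = 1, 2, 3 and pools k ≥ 4 as "polymer", keeping the
exact size distribution in `counts`. Percentages always sum to 100 within
rounding, and Σ k·n_k = N is asserted.

`detect_equilibrium()` declares the series stable from the earliest
checkpoint whose trailing percentages (through the end of the series, with
at least `window` checkpoints remaining) vary by at most `tol` percentage
points per species (default 5.0). This reads a single transient excursion —
the pattern seen in the reference equilibrium grids — as pre-equilibration
noise and declares stability immediately after it.

The hydrogen-bond counter is the standard geometric criterion (H···A
minimum-image distance ≤ 3.5 Å, D–H···A angle ≥ 130°); it exists to verify
that hydrogen bonding is marginal (a handful of bonds at most) next to the
π–π network, not to analyze hydrogen-bond dynamics.

# The apparent log K_OA

Equation and constants: `log K_OA = −ΔG_OA / (2.303 R T)` with
R = 8.314 J mol⁻¹ K⁻¹ and T defaulting to 298.15 K (298 K is equally
accepted; the difference is below 0.01 in log units for typical ΔG). The
constant 2.303 is used literally rather than ln 10 to full precision,
matching the form in which the relation is conventionally quoted; the
relative error is under 0.01%.

The combination of census and thermodynamics is genuinely underdetermined:
published analyses state that aggregate percentages and per-aggregate
ΔG_OA were combined, but not the formula. `octaggr` therefore ships two
estimators and always records which was used:

* **fraction-weighted-log** (default): Σ_s f_s · log K_OA(ΔG_s per
  molecule). Bounded by the min and max per-species values; collapses to
  the monomer value when per-molecule free energies are equal.
* **monomer-fraction**: log K_OA,monomer − log10(f_monomer), the
  thermodynamic correction obtained when the octanol phase's total burden
  is referenced to the gas-phase monomer.

An s-mer's ΔG_OA is divided by s unless the `species_thermo()` entry is
flagged `per_molecule` — this prevents double counting when quantum-chemical
values are computed for the whole aggregate. ΔG may be given in kJ/mol or
kcal/mol (factor 4.184); kJ/mol is canonical internally. Per-species ΔG_OA
values are user input throughout: no reference set is shipped, because the
values behind the published estimates are not public. For the same reason
the published estimated log K_OA column ships only as reference metadata
and is never a test target.

Both estimators are strictly increasing in the dimer fraction whenever the
dimer's per-molecule ΔG is more favorable than the monomer's, which is the
qualitative content of the concentration effect: more concentrated →
more aggregated → higher apparent log K_OA. `concentration_profile()`
flags any profile violating that monotonicity.

# Synthetic data: what it does and does not emulate

The generators produce exactly the inputs the census pipeline needs, with
known ground truth:

* `build_conformation()` plants clusters in their requested conformer
  geometry — parallel eclipsed stacks, parallel slipped stacks
  (slip ≥ 1.4 Å at the default intra-cluster distance), or alternating
  perpendicular planes — at adjacent-centroid distances safely below their
  cutoffs (defaults 3.5/3.7/4.5 Å), and scatters the rest as monomers with
  all inter-cluster centroid separations above `min_sep` (default 6 Å,
  comfortably above the 5.0 Å edge-to-face cutoff). Placement is rejection
  sampling with bounded attempts; an infeasible spec fails with a
  suggestion to enlarge the box. The template molecule is a rigid 1.40 Å
  hexagon regardless of chemical identity: the detectors see geometry, not
  chemistry. Coordinates are wrapped into the box, so the unwrap path is
  exercised by every fixture.
* `build_equilibrium_trajectory()` keeps the cluster-size multiset fixed
  while exchanging which molecules occupy which cluster (seeded identity
  swaps) and redrawing all positions each frame — a dynamic equilibrium of
  aggregation and segregation in which the census is constant although no
  molecule is permanently bound.
* `simulate_aggregation()` is a square-well Metropolis Monte Carlo toy:
  hard core σ = 3.5 Å, attractive well to 5.0 Å (also the census cutoff),
  acceptance min(1, exp(−ΔU/k_BT)) with k_B T = 0.592 kcal/mol at 298 K.
  Stacking interaction energies enter only through
  `epsilon_from_energy()` (ε = 0.10·|E|, keeping ε/k_BT ≈ 1.6–2.0 so
  association stays reversible at desk scale; full-strength energies would
  freeze aggregates irreversibly and bury the concentration trend).

What passing tests therefore show: the detector, clustering, census and
correction arithmetic are exact on configurations whose ground truth is
known, and the toy model reproduces the qualitative trends (aggregation
nondecreasing in concentration and in attraction strength). What they do
not show: that any real force field produces those percentages, solvent
structure, realistic kinetics, or aggregate geometries beyond idealized
stacks. Reproducing the reference percentages from planted end states
validates the analysis layer, not the dynamics that produced those end
states.

# Numerical choices and degenerate inputs

* Ring planes are least-squares fits by SVD of centered (unwrapped)
  coordinates; nearly collinear rings raise a degenerate-geometry error
  (second singular value below 10⁻⁸ of the largest).
* Checkpoints match the nearest frame with no interpolation; checkpoints
  outside the trajectory span are errors.
* Packing uses up to 5000 placement attempts per site; anchors are
  separated by `min_sep` plus both sites' cluster extents, which guarantees
  (by the triangle inequality in the torus metric) that no inter-cluster
  molecule pair can fall below `min_sep`.
* All stochastic code consumes R's global RNG after an explicit
  `set.seed()` from the spec/params, so identical seeds give bit-identical
  output; manifests record the seed.
* Test and report problem sizes are desk scale by design: boxes of 15–61
  molecules, trajectories of ≤ 6 frames, Monte Carlo runs of 12–28
  particles for ≤ 250 sweeps and 20 seeds per condition — large enough for
  the rank tests on the qualitative trends, small enough that the full
  suite runs in about a minute.

# Known limitations

* Orthorhombic boxes only; no binary trajectory formats (XTC/TRR/DCD).
* Whether the original recognition rule applied angle tests or only the
  three distances is not stated anywhere; with the default geometry both
  readings coincide for contact/no-contact, but conformer labels depend on
  the reconstructed angle split.
* The equal-concentration reference row for PCN-5 (60.0/40.0) is
  internally inconsistent with 12 dimers among 61 molecules (which gives
  60.7/39.3); the fixture report flags that row and excludes it from exact
  comparison rather than reproducing an arithmetic impossibility.
* The estimator modes bracket, but cannot resolve, the unpublished
  combination formula; conclusions should be checked under both.
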