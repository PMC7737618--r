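---
title: "Methods and numerical choices in elevator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical choices in elevator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each analysis stage, why the
defaults are what they are, what the synthetic generators do and do not
emulate, and the numerical conventions that make results reproducible.

## The structural model

All structural analyses operate on Cα traces (`CalphaModel`): a residue
table (chain, residue number, residue name) plus an M × 3 coordinate
matrix. Full atom sets (`AtomModel`) are used only where chemistry
matters — surface areas and heavy-atom contact distances. Coordinates
are flattened row-major, so a 3M vector is (x₁, y₁, z₁, x₂, …); every
module uses this one convention.

An elevator transporter is described by a *domain definition*: a static
`dimer_domain` (the scaffold that forms the dimer interface), a mobile
`core_domain` (the 6-TM ion-carrying bundle), a `binding_site` residue
set inside the core, and a laboratory-frame `membrane_normal` unit
vector. These are user-supplied YAML because domain boundaries are an
interpretation of the structure, not derivable from coordinates alone.

## Superposition and ensemble PCA

Superposition is the Kabsch algorithm: SVD of the masked cross-
covariance with a determinant correction so reflections are never
applied. Ensembles are built by extracting the matched (conserved-core)
residues of each structure through a correspondence table and fitting
every member onto a reference over a fit mask — typically the
dimerization domain, so that all inter-structure variance is expressed
as core motion.

PCA diagonalizes the 3M × 3M coordinate covariance with population
(1/N) normalization, computed through the SVD of the centered N × 3M
coordinate matrix; at most N − 1 eigenvalues are nonzero, and variance
fractions are invariant to the normalization choice. Projections are
plain scalar products p\_{i,k} = T\_{i0} · PC\_k with T\_{i0} the
displacement from the reference structure. Eigenvector sign is
arbitrary, so PC1's sign is calibrated by requiring a designated
outward-facing structure to project positive; other components make
their largest-magnitude coefficient positive. `project()` optionally
refuses structures whose fit-mask rmsd to the stored reference frame
exceeds a tolerance, catching un-superposed inputs.

## Elastic networks and normal modes

Two spring models over the Cα nodes:

* **cutoff-ANM** (default): every pair within R\_c = 12 Å gets a
  uniform constant k₀ = 1. The 12 Å cutoff is a mid-range value for
  Cα-only networks — small enough to keep domains distinct, large
  enough that helical bundles are rigid.
* **ED-ENM**: sequence-local pairs (separation s ≤ 3 within a chain)
  get k = 60 / s²; all other pairs within the cutoff get k = (6 / r₀)⁶.
  Local springs apply regardless of the Cartesian cutoff, so stretched
  chains never disconnect. The constants are an MD-calibrated
  parameterization in the published spirit of distance-dependent ENMs;
  they are defaults, not fitted values.

The anisotropic Hessian uses super-elements −(k/r₀²)(d ⊗ d). Six
rigid-body modes (five for collinear node sets) are removed: by the
spectral gap when it is clean (ratio > 10⁶ between the first internal
and last rigid eigenvalue), otherwise by explicit projection of the
rigid subspace before re-diagonalization. More than the expected count
of near-zero modes triggers a connectivity error naming the number of
components, because fluctuations and overlaps are meaningless on a
disconnected network. Mode involvement in a conformational change is
the absolute cosine overlap; cumulative overlap is the root-sum-square,
bounded by 1 (Bessel) and exactly 1 over a complete internal basis
(Parseval) — both bounds are tested.

## Transition pathways and the elevator metrics

`generate_pathway()` follows the iterative ENM-NMA recipe: at each
step, modes are recomputed at the current frame (self-consistent by
default), the `modes_per_step = 3` modes of highest overlap with the
remaining direction are combined by projection, the structure moves a
fixed `step_rmsd = 0.5` Å along that combination, and local geometry is
re-idealized by restoring the start structure's successive Cα–Cα
distances (one N→C pass per chain). Two details matter and are easy to
get wrong:

1. Each iteration first superposes the evolving frame onto the target
   and removes the rigid-body component of the remaining difference.
   Internal modes cannot express net translations or rotations; without
   this projection a core-only displacement (which carries net
   translational content) stalls the iteration well short of the
   target.
2. The step amplitude is capped by the remaining distance, so the
   pathway does not overshoot near convergence.

Iteration stops at coverage ≥ 0.98, at `max_iter`, or when the best
single-mode overlap falls below 0.05 (a stall, reported as such).
Coverage is primarily the PC1 projection ratio p(model)/p(target); an
rmsd-based alternative (1 − rmsd/rmsd₀) is provided because the
"fraction of transition achieved" is convention-dependent.

The **elevator shift** superposes state B onto state A over the
dimerization domain and decomposes the binding-site centroid
displacement along the membrane normal. Because the normal is a
laboratory-frame vector, the metric is only meaningful in the frame
where the normal was defined; the optional `frame` argument re-anchors
state A to that frame first, making the metric invariant under joint
rigid transforms of both inputs. Without an anchor, rotating both
structures changes the answer — this is a property of the definition,
not a bug, and is covered by a test.

## Surfaces, interfaces and contacts

SASA is Shrake–Rupley with a deterministic golden-spiral point set
(960 points/atom — the point where the single-sphere error is ~0.1%
and runtime is still negligible), probe 1.4 Å, and the vdW table
C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 Å. Unknown elements are
an error unless a radius is supplied. Buried area uses the interface
convention BSA = (S\_A + S\_B − S\_AB)/2 by default; the unhalved
"total" convention is selectable. Published interface areas from PISA
carry a ±15% tolerance here because PISA's exact parameterization is
not public.

Contact networks join core/dimer residue pairs whose minimum heavy-atom
distance is within 4.5 Å and whose conservation grades (ConSurf-style
1–9) both reach 8; residues missing from the table get grade 0 and drop
out, which is the conservative choice. Hydrophobic gate residues are
contact participants from the apolar set (Ala, Val, Leu, Ile, Met, Phe,
Trp, Pro), split into extracellular/intracellular by their position
along the membrane normal relative to the binding-site centroid.

## Trajectories and densities

Distances use the orthorhombic minimum-image convention; triclinic
boxes are rejected rather than silently mishandled. An ion is bound
when its minimum site distance is ≤ 3 Å (the carboxyl-oxygen
criterion); events are contiguous bound runs.

Density grids histogram positions into half-open voxels (a coordinate
exactly on a boundary belongs to the higher-index voxel), average
counts over frames, and convert to molar units via
c = ⟨count⟩ / (V\_voxel · 10⁻²⁷ L/ų · N\_A). Two invariants anchor the
arithmetic: total counts are conserved to machine precision, and one
particle resident in a 1 nm³ voxel reads 1.661 mol/L. OpenDX export
writes z-fastest, with grid positions at voxel centers.

## Kinetics and melting fits

The dequench percentage is read from a trace at the assay's event times
(3, 4, 5 min). Both the conventional span-normalized form
(FI₄−FI₃)/(FI₅−FI₃)·100 (default) and the literal as-printed form
(FI₄−FI₃)/(FI₅/FI₃)·100 are provided: the as-printed denominator is a
ratio and therefore dimensionally odd, so the package retains both
rather than guessing intent.

Michaelis–Menten and 4PL melting fits use Levenberg–Marquardt
(`minpack.lm`) with documented initialization: V\_max from the maximum
response and K\_M from the concentration nearest half-max; melting
plateaus from the temperature extremes, T\_m at the half-signal
crossing, slope ±10 by transition direction. The 4PL is parameterized
on linear temperature with T\_m as the EC50-analogue,
y = d + (a − d)/(1 + (T/T\_m)^b), `a` being the low-temperature
plateau. Commercial software's exact variant is not re-derivable, so
correctness is established by recovery on synthetic curves, not by
output matching.

## The synthetic generators

All generators are pure functions of (parameters, seed): they save and
restore the global RNG state, so library code never perturbs a user's
random stream. What they emulate — and what they do not:

* `make_toy_elevator()` builds a scaffold bundle (60 residues) and a
  core bundle (40 residues) of ideal α-helices (rise 1.5 Å, radius
  2.3 Å, 3.6 residues/turn), the core rigidly translated along +z
  (default 5 Å) and optionally rotated in state B. The bundles are
  antiparallel and mirror-symmetric about the y = 0 plane. That
  symmetry is deliberate: it decouples the y-shear modes (odd under the
  mirror) from the z-slide mode (even), so the elevator motion appears
  as a single clean low-frequency mode rather than mixing into shear
  combinations. The inter-bundle separation (14 Å) keeps the interface
  springs sparse relative to the intra-bundle ones — the elevator slide
  is soft, but the network stays connected. Because helices are stacked
  into bundles, successive Cα–Cα distances are canonical (≈3.8 Å)
  within helices but not across helix junctions; geometry checks in the
  tests are therefore per-helix. The toy is an idealized mechanical
  analogue, not a protein: no side chains, no membrane, no sequence.
* `make_ensemble()` adds isotropic Gaussian coordinate noise to
  discrete states — it emulates conformational heterogeneity around
  states, not continuous transition sampling.
* `make_ion_traj()` places ideal-gas ions uniformly in a periodic box
  at a stated concentration (count = round(c·N\_A·V), which makes the
  realized grid-mean concentration exactly reproducible), with one
  designated ion held within the binding threshold for a chosen
  fraction of frames in contiguous blocks. There is no electrostatics,
  no excluded volume and no diffusion model; the generator exists to
  give binding classification and density analysis a known answer.
* `make_kinetics()` and `make_melt()` evaluate the closed-form models
  with multiplicative (kinetics) or plateau-scaled additive (melt)
  Gaussian noise.

Problem sizes in the examples and acceptance script (100-residue toy,
500-frame / (100 Å)³ trajectories, 200 fit replicates) are the
package's own choices, sized so every analysis completes in seconds on
one CPU while keeping statistical bands meaningful.

## Reproducibility conventions

Structure files round-trip through a hand-rolled fixed-column PDB
writer (hybrid-36 for residue numbers > 9999 and serials > 99999, 3
decimal places — hence millidangstrom round-trip tolerance in tests).
CSV outputs from the CLI format numbers with `%.10g`, making fixed-seed
runs byte-for-byte reproducible, which is asserted in the test suite.
Every CLI run writes `run_config.json` recording the effective
configuration.

## Limitations

* Cα elastic networks describe collective geometry, not energetics;
  eigenvalues are in relative units unless the user supplies a scale.
* The pathway generator is a geometric interpolator guided by modes; it
  does not estimate barriers or kinetics.
* SASA-based interface areas depend on the radius table; comparisons
  with other software should allow ~15%.
* The minimum-image code supports orthorhombic boxes only.
* Deposited-structure analyses require the user to supply coordinate
  files, a residue correspondence and a domain definition; the package
  ships none of these.
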