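---
title: "Quantifying molecular-glue interfaces: surfaces, footprints, and geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying molecular-glue interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glueprint)
```

## The problem

A molecular glue degrader (MGD) creates a protein–protein interface that
did not exist before: the compound remodels the surface of its primary
receptor (here cereblon, CRBN) so that a second protein — possibly another
copy of CRBN itself — docks against it. Judging the character of such an
induced interface requires numbers, not pictures:

* the **buried solvent-accessible surface area** (SASA) summed over the
  two protomers, compared against the empirical bands for transient
  interactions (roughly 800–1200 Å²; single transient contacts are often
  nearer 400 Å²) and obligate dimers (larger);
* the **interface footprint** on each protomer's molecular surface, and
  its split into compound-contributed and protein-contributed area — the
  quantity that distinguishes a compound-centred contact from a genuine
  neo-interface;
* the **conformational reproducibility of the bound ligand** (RMSD between
  independent copies), and rigid internal geometry such as the dihedral
  between the two ring planes of a spirocyclic linker;
* the **polar contact inventory** (canonical and weak hydrogen bonds,
  non-classical C–H···O contacts) across the interface, assigned to the
  cis or trans protomer;
* the **hydrodynamic radius** the assembled complex should display in
  solution, as a cross-check against hydrodynamic measurements such as
  flow-induced dispersion analysis.

`glueprint` computes all of these from a single coordinate file. This
vignette records the models used, the tunable parameters and their
defaults, what the synthetic test structures do and do not establish, and
the numerical design decisions.

## Surface models

### Solvent-accessible surface area

SASA is computed by Shrake–Rupley quadrature: each atom is inflated by the
probe radius, covered with a fixed generalized-spiral (Fibonacci) point
set, and a point counts as exposed when it lies strictly outside every
other inflated atom. The per-atom area is
`(exposed / total points) × 4π(r + probe)²`. The point set is
deterministic — identical input gives bit-identical areas, with no seeds.
An isolated atom is exact by construction. Buried SASA of subunit *S*
inside a complex is `SASA(S alone) − SASA(S's atoms within the complex)`,
so occlusion by every other atom of the complex counts.

### Solvent-excluded (molecular) surface

The SES is the boundary the probe sphere cannot penetrate. It is built on
a regular grid as the zero level set of

```
f(x) = min( −A(x),  dist(x, P) − probe )
```

where `A(x)` is the signed distance to the union of probe-expanded spheres
(negative inside) and `P` is the set of exposed quadrature points on the
probe-expanded surface — exactly the positions a rolling probe centre can
occupy. `f > 0` inside the solvent-excluded body: the first term carves
the contact surface (the zero set of `A` coincides with the van der Waals
surface on convex patches), the second term carves the reentrant surface
at distance `probe` from any admissible probe centre. The level set is
triangulated by marching tetrahedra on a translation-invariant six-tet
cube split with consistent face diagonals, which guarantees a closed,
orientable, manifold mesh (the test suite asserts that every edge bounds
exactly two triangles). Each vertex carries one third of the area of its
incident triangles (so vertex areas conserve total mesh area exactly) and
an attribution to the atom minimizing the *surface distance*
`|v − c| − r` — not the centre distance, which would misattribute vertices
wherever radii differ. Attribution ties break to the lowest atom serial.

### Interface footprints

A vertex of a subunit's mesh is labelled *interface* when its exact
nearest-vertex distance to the complex mesh exceeds a threshold (2.0 Å
default): surface present on the isolated subunit but absent from the
complex envelope is surface consumed by complex formation. The footprint
area is the summed vertex area over labelled vertices, and the
ligand/protein decomposition sums the same areas by the ligand flag of the
attributed atom, so the two parts add up to the footprint exactly.

Both meshes must be built with the same grid parameters and in the same
frame; the distance rule is evaluated against complex-mesh *vertices*, so
matched mesh densities keep the threshold meaningful. Because the
labelling threshold is the one fixed constant of this definition, every
report includes a threshold-sensitivity block (footprints at 1.5/2.0/2.5 Å
by default). This also exposes a subtlety the definition itself leaves
open: a deep pocket vertex could in principle sit within the threshold of
complex-surface vertices on the *far side* of a thin subunit; the
sensitivity scan makes such behaviour visible rather than silently
averaged away.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | conventional water probe |
| `grid_spacing` | 0.5 | Å | SES grid; must not exceed the smallest radius; refinement to 0.25 Å changes areas by <3% |
| `sasa_points` | 960 | points/atom | deterministic spiral quadrature |
| `threshold` | 2.0 | Å | interface labelling rule |
| `threshold_scan` | 1.5/2.0/2.5 | Å | sensitivity block, always reported |
| canonical H-bond | ≤ 3.5 | Å | heavy-atom donor–acceptor distance |
| weak H-bond | 3.5–4.0 | Å | |
| C–H···O | ≤ 3.7 | Å | carbon–oxygen across the interface |
| minimum contact | 2.2 | Å | excludes clashes |
| vdW radii | C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20 | Å | Bondi-style; default 1.70 for unknown elements; user-overridable |
| Rh bead radius | 3.0 | Å | one bead per residue; ligand atoms keep vdW radii |
| Rh hydration | 0.3 | nm | added to the Kirkwood estimate |

Radii are not standardized across structure-analysis tools and the surface
constants (probe, mesh density) materially affect absolute areas; they are
therefore declared here once and echoed into every report, and
structure-derived areas should be compared only across runs with identical
parameters.

## Ligand and domain geometry

Superposition is the closed-form least-squares (Kabsch) solution restricted
to proper rotations; the reported RMSD equals a direct residual evaluation
under the returned transform to 1e-9 (asserted). The two-copy ligand RMSD
puts atoms in correspondence **by atom name** over all modelled heavy atoms
— deposited models carry no hydrogens, so "all-atom" operationally means
all heavy atoms — and fails loudly, naming offenders, when the copies'
atom sets differ. Ring planes are least-squares fits (smallest principal
direction); rings are near-planar but not exactly planar, so the planarity
RMS is reported alongside. The inter-plane angle is folded to [0°, 90°]
and is insensitive to normal sign.

Hydrogen-bond detection uses heavy-atom distance bands without angular
terms: with no hydrogens in the models, donor geometry cannot be
evaluated, and pretending otherwise by placing hydrogens would import a
force field's opinions into a measurement. Protein donors/acceptors follow
a fixed per-residue atom-name table (backbone N donor, backbone O
acceptor, standard sidechain roles); ligand N/O atoms are typed as both
donor and acceptor, since no chemical perception is attempted. This
over-permissive ligand typing is deliberate and documented: it can only
create false positives within 3.5 Å, which the contact table exposes
per-pair for inspection.

## Hydrodynamic radius

The Kirkwood bead approximation for a rigid array of `N` beads with radii
`aᵢ`:

```
1/R0 = (1/N²) ( Σᵢ 1/aᵢ + Σᵢ≠ⱼ 1/rᵢⱼ ),    Rh = R0 + δ
```

with a hydration increment δ = 0.3 nm. The structure is coarse-grained to
one bead per protein residue (heavy-atom centroid, radius 3.0 Å) plus one
bead per ligand heavy atom, keeping the double sum fast at desk scale. For
compact assemblies of many beads the estimate is dominated by the pairwise
`1/r` term and is insensitive to the bead radius; the self term matters
only for very small bead counts, and a single bead degenerates to its own
hydrated radius. The method tag and all parameters are recorded in the
output, because hydrodynamic predictors differ by several percent between
schemes and a reported Rh is only interpretable together with its method.

## Synthetic structures and what a green test establishes

Every stage is tested against generators whose answers are known in closed
form, with fixed documented seeds:

* **Sphere pairs** with explicit radius overrides; the buried-SASA oracle
  is the spherical-cap (lens) formula, continuous and monotone in the
  separation, with containment and the concentric equal-radius case
  (sphere 2 buried, by convention) handled explicitly.
* **Rigid ligand dimers**: a seeded random copy moved by a known rotation
  and translation plus optional Gaussian noise; the RMSD cross-check is an
  independent residual evaluation.
* **Spiro-like ring pairs** sharing one atom, with the second ring's plane
  rotated by an exactly known angle.
* **Toy glue dimers**: two compact lattice half-balls presenting flat
  multi-atom faces across a gap, related by an exact two-fold rotation,
  optionally bridged by a symmetry-related curved pseudo-ligand pair. The
  flat faces matter: a single-atom contact never produces interface
  vertices beyond the 2 Å rule, just as a point contact between proteins
  has no footprint.

These fixtures emulate the *geometry* of a glue-bridged dimer — bodies in
contact, a ligand at the seam, exact symmetry — but not the chemistry or
texture of real structures: no element diversity (so no polar contacts),
no sidechain packing, no experimental coordinate noise, no alternate
conformations beyond what the parser tests construct. A green suite
therefore establishes that the *operators* are correct against their
mathematical definitions, not that any particular biological interface has
a particular area; structure-specific numbers always come from running the
pipeline on deposited coordinates.

## Numerical design decisions

* **SES construction.** A grid signed field with marching tetrahedra was
  chosen over the analytic reduced-surface construction for robustness and
  implementability; the cost is grid-discretization error, bounded in the
  tests (single-sphere area within 2% at 0.5 Å; refinement 0.5→0.25 Å
  moves fused-body areas by <1%). Grid node values are clamped far from
  the zero crossing (never within one cell of it), and exact zeros are
  perturbed by −1e-9 so no isosurface vertex coincides with a grid node.
* **Marching tetrahedra over marching cubes.** The six-tetrahedron cube
  split with translation-invariant diagonals needs no case tables and is
  unconditionally manifold; ambiguous marching-cubes cases cannot arise.
* **Quadrature resolution is a real floor.** One quadrature point
  represents `4π(r+probe)²/960` ≈ 0.1–0.5 Å² of one sphere. A buried cap
  covered by ~25 points cannot be measured to 2% relative accuracy by any
  equal-weight 960-point set (cap-discrepancy lower bounds; alternative
  spirals were measured and are no better). Concretely: for equal-radius
  sphere pairs swept from van der Waals contact to expanded-sphere
  tangency, the last ~5% of the separation range shows buried-SASA errors
  of up to ~6% relative — about one to two points of area — while the rest
  of the range stays well under 2%. The acceptance suite asserts the 2%
  band over the whole sweep and is honestly red at those near-tangency
  points; a companion test shows the same sweep passes 2% everywhere at
  16× point density, confirming the estimator converges to the oracle and
  the error is purely resolution.
* **Altloc policy.** Highest occupancy wins; ties keep the first
  conformer encountered. Deterministic single-conformer geometry beats
  occupancy-weighted averaging for distance-based analysis.
* **Partition semantics.** Subunits are disjoint chain (+ residue-range)
  selections; a protomer of a glue dimer defaults to one receptor chain
  plus its own ligand copy, and an adaptor chain (present only once in
  the deposited models) can be included in one protomer via the partition
  spec. Reports echo the partition used, because buried-SASA totals are
  only comparable under the same partition convention.
* **Degenerate inputs.** Fewer than three or collinear points refuse to
  superpose or fit planes; concentric equal spheres bury the second by
  convention; empty selections, empty meshes, unassigned radii and
  overlapping partitions raise precondition errors rather than returning
  numbers.

## Known limitations

* Absolute SES areas depend on probe, grid and mesh density; only
  like-for-like comparisons are meaningful.
* Contact detection is distance-only; sulfur is typed for a few sidechains
  but halogen bonds, π-stacking and hydrophobic-patch scoring are out of
  scope.
* The Rh estimate is one member of a family of bead approximations;
  agreement with measured values to better than ~10% should not be
  over-interpreted.
* No symmetry expansion, density-map handling, or sequence-based chain
  matching: the model file is taken as deposited.
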