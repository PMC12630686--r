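# glueprint

Structural-interface analysis for molecular-glue induced protein complexes.

Molecular glue degraders (MGDs) are small molecules that remodel a protein
surface so that a second protein is recruited — in the motivating system, two
glue molecules bound in the tri-tryptophan pockets of two cereblon (CRBN)
molecules bridge a CRBN homodimer on its CRL4 ligase. Assessing whether such
an induced interface is a weak crystal contact or a biologically meaningful,
obligate-like dimer comes down to a handful of structure-derived numbers:
how much solvent-accessible surface is buried, how large the interface
*footprint* on each protomer is, how much of that footprint is contributed
by the compound versus by protein–protein contacts, how reproducible the
bound ligand conformation is, which polar contacts hold the assembly
together, and what hydrodynamic radius the assembly should show in solution.

`glueprint` computes all of these from atomic coordinates (PDB or mmCIF),
with every stage testable offline against synthetic structures with
closed-form oracles.

## What it computes

- **SASA** — deterministic Shrake–Rupley quadrature on probe-expanded
  spheres (960 generalized-spiral points/atom, probe 1.4 Å by default);
  per-atom areas, exact for isolated atoms.
  Buried SASA of a subunit S in a complex is
  `SASA(S alone) − SASA(S within the complex)`.
- **SES (molecular surface) meshes** — probe-rolling signed-distance field
  on a regular grid (0.5 Å default), isosurfaced by marching tetrahedra
  into a closed, orientable triangle mesh with per-vertex areas and
  nearest-atom attribution.
- **Interface footprints** — a subunit-mesh vertex is *interface* when its
  exact nearest-vertex distance to the complex mesh exceeds 2.0 Å; the
  footprint area is the summed vertex area, decomposed exactly into ligand
  and protein contributions via the vertex→atom attribution. Total buried
  SASA is classified against the published bands for transient
  (800–1200 Å²) vs obligate-range interfaces.
- **Ligand geometry** — Kabsch least-squares superposition (proper
  rotations only); all-heavy-atom RMSD between the two copies of a bound
  ligand; least-squares ring-plane fits and the inter-plane (spiro
  dihedral) angle in [0°, 90°].
- **Polar contacts** — geometric donor/acceptor typing with heavy-atom
  distance bands: canonical H-bond ≤ 3.5 Å, weak H-bond 3.5–4.0 Å,
  non-classical C–H···O ≤ 3.7 Å; records labelled cis/trans relative to
  the protomer owning the ligand.
- **Hydrodynamic radius** — Kirkwood bead-model double sum
  `1/R0 = (1/N²)(Σ 1/aᵢ + Σ_{i≠j} 1/rᵢⱼ)` over one bead per residue plus
  one per ligand atom, plus a declared 0.3 nm hydration increment.

## Worked example

A seeded synthetic glue dimer (two compact pseudo-domains bridged by a
two-copy pseudo-ligand, related by an exact two-fold):

```r
library(glueprint)
tc <- make_toy_complex(n_per_subunit = 30, gap = 1.0,
                       ligand_at_interface = TRUE, seed = 17)
report <- analyze_complex(analysis_config(
  input = tc$model, partition = tc$partition, ligand_codes = "LIG",
  cis_chains = "A", label = "toy_glue_dimer"))
print(report)
#> <AnalysisReport 'toy_glue_dimer': 70 atoms>
#>   buried SASA 241.3 A^2 (below-transient)
#>   P1: footprint 10.9 A^2 (ligand 8.9 / protein 2.0)
#>   P2: footprint 11.0 A^2 (ligand 8.7 / protein 2.2)
#>   ligand-pair RMSD 0.000 A (5 atoms)
#>   contacts: 0 canonical, 0 weak, 0 C-H...O
#>   predicted Rh 0.81 nm (kirkwood_beads)
```

Reading the numbers: complex formation buries 241 Å² of SASA summed over
both protomers — far below the 800–1200 Å² transient band, as expected for
a 70-atom toy. Each protomer's footprint (surface present on the isolated
subunit but absent from the complex surface, 2.0 Å rule) is ~11 Å², of
which ~9 Å² is contributed by the bridging pseudo-ligand. The two ligand
copies are exactly congruent (RMSD 0 by construction), no polar contacts
are found (every toy atom is carbon), and the Kirkwood bead model predicts
a 0.81 nm hydrodynamic radius. `write_report(report, "out/")` serializes
the JSON report plus CSV tables; the two-fold symmetry of the construction
shows up as the near-equality of the P1/P2 rows.

On a deposited glue-dimer model the same call — with the partition set to
one CRBN chain plus its ligand copy per protomer
(`--subunit P1=A:LIG ...`), or including the DDB1 adaptor via the partition
spec — reports the buried SASA, per-protomer footprints with their MGD
share, the ligand-pair RMSD, the spiro ring dihedral (pass the two ring
atom-name sets as `ring_atoms`), the cis/trans contact inventory, and the
predicted hydrodynamic radius of the ternary complex.

## Command line

```sh
Rscript inst/cli/glueprint.R analyze model.pdb \
  --ligand-code LIG --subunit P1=A --subunit P2=B \
  --probe 1.4 --grid 0.5 --threshold 2.0 --cis-chains A --out out/
Rscript inst/cli/glueprint.R compare --manifest structures.tsv --out out/
```

## Vignette

`vignettes/interface-analysis.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, what the synthetic
generators do and do not emulate, and the numerical design choices
(including the known resolution limit of the 960-point SASA quadrature for
near-tangent sphere pairs).
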