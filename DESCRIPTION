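Package: glueprint
Title: Interface Footprints and Geometry for Molecular-Glue Ternary Complexes
Version: 0.1.0
Authors@R: person("glueprint", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Structural-interface analysis of molecular-glue induced protein
    complexes from atomic coordinates. Reads PDB and mmCIF models, computes
    solvent-accessible surface areas (deterministic Shrake-Rupley quadrature),
    triangulated solvent-excluded (molecular) surfaces on a probe-rolling
    signed-distance grid, buried surface areas and interface footprints with
    ligand/protein decomposition, rigid-body superpositions and RMSDs,
    ring-plane dihedrals, geometric polar-contact inventories, and
    Kirkwood bead-model hydrodynamic radii. Ships synthetic-structure
    generators with closed-form oracles so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
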