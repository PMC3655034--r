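Package: protideal
Title: Protein Structure Idealization in Dihedral-Angle Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds, for a target protein structure, an idealized structure
    whose bond lengths and bond angles all take their tabulated mean
    (Engh-Huber) values, so that the conformation is fully determined by
    dihedral angles.  The backbone is optimized by a tail-grid dynamic
    program over discretized candidate coordinates that maximizes a score
    combining a per-residue Ramachandran log-odds term with frame-fixed
    RMSD penalties to the target (C-alpha, C-beta, hydrogen-bond atoms,
    and phi/psi angles).  Side chains are idealized residue-by-residue by
    exhaustive chi-angle grid search against a rotamer library.  Includes
    tools to build Ramachandran probability tables from structures, read
    backbone-dependent rotamer libraries, detect backbone hydrogen bonds
    by the Kabsch-Sander criterion, and generate synthetic test peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
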