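Package: dotrna
Title: Disorder-to-Order Transition Analysis at Protein-RNA Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects disorder-to-order transition (DOT) regions in
    RNA-binding proteins by comparing missing-residue records between a
    free protein structure and its RNA-bound complex, and characterises
    how those regions recognise RNA. Provides interface contact detection
    at literature distance cutoffs (3.5 and 6 Angstrom), per-residue
    binding frequencies and propensities with complex-level bootstrap
    standard errors, Shrake-Rupley solvent accessibility with relative
    accessibility references, protein and RNA secondary-structure
    cross-tabulations (DSSP-style letters and dot-bracket strings with
    pseudoknots), and a pairwise Lennard-Jones plus Coulomb interaction
    energy scorer for amino-acid/nucleotide contacts. Ships a synthetic
    structure generator that writes free/bound PDB pairs with known
    ground truth so every pipeline stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
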