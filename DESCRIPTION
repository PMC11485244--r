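Package: densid
Title: Protein Identification from Cryo-EM Side-Chain Density by Degenerate
    Motif Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying the protein behind an unassigned chain in a
    cryo-EM reconstruction from the ambiguity classes that its side-chain
    densities allow. Degenerate residue patterns in bracket-class syntax are
    parsed, scanned against FASTA proteomes with overlap semantics, and scored
    with background match probabilities, expected hit counts, information
    content and uniqueness probabilities. A resolution-tiered confusion model
    simulates pattern derivation from density and measures identification
    recovery on seeded synthetic decoy proteomes. Companion chain-level
    analyses cover segment masses, residue composition, fragment-boundary
    estimation from apparent mass, in-silico chymotryptic digestion with
    missed cleavages, helical twist/rise/crossover geometry of amyloid
    filaments, and inter-chain interface characterization (contacting side
    chains, hydrophobic fraction, hydrogen bonds, ordered solvent) from PDB
    and mmCIF atomic models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
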