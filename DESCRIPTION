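Package: mlascan
Title: Deep Mutational Scanning and Interface Analysis of the MlaC Lipid Carrier
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for deep mutational scanning (DMS) of the
    periplasmic lipid carrier MlaC and the protein-protein interfaces it uses
    to shuttle phospholipids between the inner and outer membranes of
    Gram-negative bacteria. Implements site-saturation NNS library
    enumeration, amplicon read preprocessing and variant counting,
    counts-per-million normalisation, enrichment-based fitness scoring
    (log frequency ratios anchored to wild type), selection of functionally
    important residues, 4 Angstrom inter-chain contact mapping on predicted
    complex models with hinge-angle and inward/outward conformation analysis,
    and global 1:1 Langmuir fitting of biolayer-interferometry sensorgrams.
    A synthetic-data module generates NNS libraries, selection outcomes,
    sequencing reads, sensorgrams and toy two-chain complexes with known
    ground truth so that every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
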