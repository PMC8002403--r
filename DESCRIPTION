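Package: peptools
Title: Peptide Sequence, Structure and Library Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bioinformatics and cheminformatics toolkit for peptides.
    Computes physico-chemical descriptors (Henderson-Hasselbalch net charge,
    isoelectric point, Eisenberg hydrophobicity, ProtParam aromaticity and
    instability index, SMILES-derived molecular weight, Wildman-Crippen logP
    and hydrogen-bond counts), screens sequences against empirical solubility
    and synthesis rules, performs gap-free position-by-position alignments
    under substitution matrices, builds 3D peptide conformers by distance
    geometry with MMFF94 cleanup, analyses protein-peptide complexes
    (secondary structure, accessible surface area, non-bonded contacts,
    hydrogen-bond interaction graphs) and designs combinatorial peptide
    libraries with HELM notation support for D-amino acids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    ChemmineOB,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
SystemRequirements: Open Babel (obabel, obenergy) for SMILES descriptors,
    canonicalization and MMFF94 conformer cleanup
Config/testthat/edition: 3
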