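# peptools

Peptides sit awkwardly between two tool ecosystems: they are chains of
amino acids like proteins, yet in drug discovery they are handled as
ligands — scored, filtered and enumerated like small molecules.
`peptools` is an R toolkit for people working on peptide screening,
developability triage and protein–peptide structural analysis that
covers both views in one package:

* **Sequence**: physico-chemical descriptors (Henderson–Hasselbalch net
  charge at any pH, isoelectric point by bisection, summed Eisenberg
  hydrophobicity, ProtParam aromaticity/instability index, and
  SMILES-derived molecular weight, Wildman–Crippen logP and
  hydrogen-bond donor/acceptor counts), plus empirical solubility and
  synthesis rule screening.
* **Chemistry**: deterministic sequence → SMILES construction with
  backbone-ordered atoms (D-amino acids supported via `[dX]` tokens and
  HELM notation), and single-conformer 3D prediction by distance
  geometry with MMFF94 cleanup, written as residue-ordered PDB.
* **Structure**: protein–peptide complex analysis — per-residue
  secondary structure and relative accessible surface area (native
  Kabsch–Sander + Shrake–Rupley implementations), non-bonded contact
  profiles at a distance threshold, and weighted hydrogen-bond
  interaction graphs with publication-style rendering.
* **Libraries**: combinatorial design by pattern expansion
  (`"XRTEX"` → 400 sequences), single-position scans, and seeded
  frequency sampling, with per-position frequency matrices for logos.
* **Alignment**: gap-free position-by-position scoring under
  substitution matrices (BLOSUM62 ships with the package), the model of
  choice when peptides are ligands rather than homologues.

The net charge model sums
`+1/(1+10^(pH−pKa))` over basic groups and `−1/(1+10^(pKa−pH))` over
acidic groups (Lehninger side-chain pKa, termini 9.0/2.0); the
hydrogen-bond energy between backbone amides is the Kabsch–Sander
electrostatic term `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
kcal/mol with bonds below −0.5 kcal/mol.

## Worked example

```r
library(peptools)

property_report("KLLFKSAGW")
#> <property_report> KLLFKSAGW (9 residues)
#>   net charge (pH 7.0):  1.990
#>   molecular weight:     1049.265 g/mol
#>   Crippen logP:         4.465
#>   hydrophobicity (sum): 2.040
#>   aromaticity:          0.222
#>   instability index:    -3.533
#>   isoelectric point:    10.554
#>   H-bond donors/acceptors: 14 / 23
#>   rules failed: 2 solubility, 0 synthesis
```

The two lysines and the free amino terminus put the charge near +2 at
pH 7, which already trips the |charge| > 1 solubility rule; the
charged+basic composition pushes the isoelectric point to 10.6. The
molecular weight and logP come from the peptide's SMILES via Open
Babel, not from residue-mass tables, so modified termini or D-residues
are priced correctly.

```r
r <- align_positionwise("KLLFKSAGW", "KILFRSTGW")
r
#> <alignment_result> KLLFKSAGW vs KILFRSTGW  [BLOSUM62]
#>   score 40, 6/9 identical, 8/9 similar
similarity_fraction(r)
#> [1] 0.889
```

Structure mode works on any PDB complex; a synthetic-fixture generator
makes the analysis reproducible without downloads:

```r
f <- make_fixture_complex("helix", seed = 1)   # chains A (protein), C (peptide)
m <- load_complex(f, "C")
count_contacts(m, 4.0)          # per-residue interface atom pairs
annotate_structure(m, "C")      # DSSP-alphabet codes + relative ASA
g <- hydrogen_bond_graph(m)     # weighted interface H-bond graph
render_graph(g, "hbonds.png")
```

A command-line wrapper mirrors the library:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/peptools.R", package="peptools"))') \
    -m sequence -s KLLFKSAGW -o out/
```

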