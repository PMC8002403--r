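---
title: "Models and methods behind peptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

peptools treats a peptide from three complementary viewpoints: as a
sequence of monomers (bioinformatics), as a small molecule
(cheminformatics), and as a partner in a protein complex (structural
analysis). This vignette explains the models behind each viewpoint, the
parameters that matter, and the choices made where the design was
genuinely open.

## The peptide data model

A `peptide` is an ordered list of monomer codes drawn from a registered
table: the 20 canonical L-amino acids plus their D-counterparts, written
in bracket notation (`A[dA]G`). Lowercase one-letter input is
normalized to uppercase L-residues; D-residues must be bracketed. This
asymmetry is deliberate: a silent convention where lowercase means
D-configuration would make case errors chemically meaningful. The
monomer table is the single source of truth for per-residue constants —
masses, side-chain pKa values, hydrophobicity, category flags — so every
downstream number can be traced to one place and pinned in tests.

Cyclic topology is a flag: it changes the HELM connection section and
the interaction-graph layout hint, but SMILES output is always the
linear peptide. Cyclic SMILES closure is a known limitation of this
version.

## Net charge and isoelectric point

Net charge at a given pH is the Henderson–Hasselbalch sum over
ionizable groups: each basic group (His, Lys, Arg side chains, the free
alpha-amino terminus) contributes $+1/(1+10^{pH-pK_a})$ and each acidic
group (Asp, Glu, Cys, Tyr side chains, the alpha-carboxyl terminus)
contributes $-1/(1+10^{pK_a-pH})$. Side-chain pKa values are the
Lehninger set; the termini are fixed at 9.0 and 2.0. Which published
pKa table to use is an open choice — different tables shift a peptide's
charge by a few tenths of a unit — so the table is pinned once and
recorded in every report header.

The isoelectric point is found by bisection of the net-charge function
on [0, 14] (at most 64 halvings, stopping at |charge| < 1e-4). Because
the charge function is continuous, strictly positive at pH 0 (the
amino terminus) and strictly negative at pH 14 (the carboxyl terminus),
a root always exists, and bisection makes the pI exactly
self-consistent with `net_charge()` — a property the test suite
verifies on random peptides rather than assuming.

Histidine is treated two ways on purpose: categorically "charged" for
the empirical rules (which count residue types) and fractionally
charged for the Henderson–Hasselbalch sum (pKa 6.0 gives it ~0.09 at
pH 7). Rule logic stays discrete; charge logic stays continuous.

## Hydrophobicity, aromaticity, instability

Hydrophobicity is the **sum** of Eisenberg consensus values over
residues, not the mean. The summed convention makes the score additive
over concatenation and proportional to length for homopolymers, which
is how the descriptor behaves in the wild for peptide-library screening
(a 15-mer's score is ~15 times a per-residue mean).

Aromaticity is the fraction of Phe/Trp/Tyr. The instability index is
the Guruprasad dipeptide statistic $(10/L)\sum_i \mathrm{DIWV}(x_i,
x_{i+1})$ with the published 20×20 weight table; it is undefined for
single residues, where the package warns and returns `NA` for that
field only.

## SMILES construction and molecular descriptors

Sequence → SMILES emits one fixed unit per residue from N- to
C-terminus — `N[C@@H](side chain)C(=O)` with glycine and proline
special-cased — and terminates with the free acid. Because the
construction is deterministic and unit boundaries are unambiguous, the
residue sequence can be decoded back from the string by walking the
backbone amides; the round trip is tested for all homodimers and random
10-mers. Stereo tags default to L and are inverted per-unit for
D-residues; every unit's tags were verified by canonicalizing the
single-residue peptide against reference isomeric SMILES of the free
L-amino acids.

Molecular weight, Wildman–Crippen logP and hydrogen-bond donor/acceptor
counts are computed from the SMILES via Open Babel. Donors and
acceptors follow an explicit Lipinski-style convention — donors are N/O
atoms bearing at least one hydrogen (`[#7,#8;!H0]`), acceptors all N/O
atoms (`[#7,#8]`) — recorded in the report metadata, because toolkit
defaults differ and the counts are only comparable under a stated
convention.

## Empirical solubility and synthesis rules

Three solubility rules: charged fraction > 45%, hydrophobic fraction
> 45%, |net charge at pH 7| > 1. All thresholds are strict
inequalities ("exceeds", "more than"), so a sequence at exactly 45%
passes — the boundary case is in the acceptance suite. The charged set
is D,E,K,R,H and the hydrophobic set A,I,L,M,F,W,V,Y, shared with the
monomer-table flags.

The synthesis rule set (v1) registers the sequence liabilities screened
in synthesis practice: runs of ≥4 identical residues, aspartate
cleavage motifs DG/DP, N-terminal Gln/Asn (cyclization/deamidation),
a predominantly uncharged sequence (>75% of 5-residue windows without
a charged residue), and ≥2 oxidation-prone residues (Met/Cys/Trp).
The registry is versioned and each rule reports its evidence span, so
the set can evolve without silently changing old reports.

## Gap-free alignment

Peptides compared as ligands do not share the evolutionary model behind
gapped alignment, so the aligner scores equal-length pairs
position-by-position: the score is exactly $\sum_i s(a_i, b_i)$ under a
substitution matrix in NCBI text layout (BLOSUM62 ships with the
package). Unequal lengths are an error, never a truncation. "Similar"
means a strictly positive matrix score; the similarity fraction is the
share of similar positions. Position-specific weighting beyond plain
matrix lookup is an extension point, not implemented.

## Conformers by distance geometry

A single 3D conformer is predicted from sequence in five steps: (1) the
heavy-atom bond graph comes from per-residue topology tables (the same
tables that give PDB atom names); (2) a distance-bounds matrix is built
— bond lengths ±0.02 Å, geminal distances from ideal angles ±0.06 Å,
a 2.4 Å clash floor elsewhere — and smoothed with triangle inequalities;
(3) a random distance matrix within bounds is drawn from the seed;
(4) classical metric embedding (3 dominant eigenvectors) gives initial
coordinates, refined by L-BFGS against the bounds with a reflection
step that restores majority-L chirality; (5) Open Babel adds hydrogens
and minimizes with MMFF94 (static variant, 500 steepest-descent steps),
after which hydrogens are stripped by default. Embedding is retried up
to 10 times before an error. The MMFF94 energy of the minimized
conformer is recorded in kcal/mol.

The embedding does not enforce stereochemistry beyond the global
reflection, so individual side-chain centers can invert in rare
samples; bond lengths, angles and clash distances are always restored
by the force field and are what the tests assert. Conformer ensembles,
docking and solvent models are out of scope.

## Complex analysis

PDB complexes are parsed with bio3d: first model only, ATOM records
only (waters and ligands excluded), alternate location A kept. The
peptide chain is named by the caller; everything else is protein.

**Contacts.** A contact is an atom pair — one heavy atom in a peptide
residue, one in any protein residue — within a threshold (default
4.0 Å, inclusive). The profile counts pairs, not contacting atoms, so
one peptide atom near three protein atoms counts three; the
alternative reading is deliberately not the default. Hydrogens are
excluded by default because crystal structures usually lack them.

**Secondary structure and H-bonds.** The package implements the
Kabsch–Sander model natively: amide hydrogens are placed 1 Å from N
along the preceding carbonyl's O→C direction, and the electrostatic
bond energy $E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} -
1/r_{CN})$ kcal/mol assigns a bond when $E < -0.5$ kcal/mol (the
model's own cutoff). The donor's covalently linked preceding residue
is excluded — its 1.33 Å C–N distance would otherwise fabricate a
bond. Secondary structure follows the turn/bridge patterns (alpha
helix from consecutive 4-turns, 3-10 and pi analogously, strands from
bridge ladders, turns and bends), with helix codes taking priority.
Accessible surface area is Shrake–Rupley with 256 sphere points per
atom and a 1.4 Å probe; relative ASA divides by the Tien et al.
theoretical maxima and clamps to [0, 1], and the normalization table
is recorded in the report metadata since raw ASA conventions differ
between implementations.

**Interaction graph.** Residues are nodes, hydrogen-bond counts are
edge weights. The interface graph keeps only bonds crossing the
peptide/protein boundary; intra-chain bonds (helical i,i+4) are an
option. Peptide nodes are always present, protein nodes only when
bonded. Rendering colours peptide nodes yellow and protein nodes by
chain, draws width proportional to weight, and is deterministic under
a fixed layout seed; cyclic peptides switch the layout hint to
Fruchterman–Reingold.

## Synthetic fixtures

All structure tests run on generated PDB complexes — no downloads. The
generator builds ideal-geometry poly-alanine backbones by
internal-coordinate chaining (bond lengths 1.458/1.525/1.329 Å, angles
111.2/116.2/121.7°) with phi/psi set per kind: an alpha-helix pair
(−57, −47) at a 3.8 Å interface gap, an extended strand pair
(−139, 135), an antiparallel strand pair registered for mutual
backbone hydrogen bonding, a two-atom kind with exactly one interface
pair at a stated distance, and a far-apart kind (60 Å) with no
interface at all. A seeded 0.001 Å coordinate jitter makes each seed's
file unique yet byte-reproducible, without disturbing any geometric
property the fixtures guarantee.

These fixtures emulate clean idealized geometry. Real complexes have
side-chain diversity, missing atoms, alternate conformations and
non-ideal hydrogen-bond geometry, so passing tests demonstrate
correctness of the algorithms, not robustness to crystallographic
pathology beyond the altloc/HETATM filters exercised.

## Library design

Pattern expansion is the exact Cartesian product over `X` positions
(refused above $10^7$ sequences — a six-X pattern over 20 residues
already exceeds it); the single-position scan substitutes every residue
at every position of a base; frequency sampling draws i.i.d. per
position from given rows under a seed. Outputs are deduplicated and
sorted so identical designs produce identical files. The frequency
matrix (observed fractions per position) is the data behind a sequence
logo; rendering the logo itself is left to plotting backends.

## Problem sizes and numerical choices

The test and acceptance suites use 100–1000 random peptides per
sequence-level property, 500 alignment pairs over three matrices, 20
random atom clouds for contact oracles, 10 000 samples for uniformity
checks, and 20 seeds of a 5-mer for conformer robustness — sizes at
which every stochastic bound tested has comfortable margin while the
whole suite stays fast. Bisection tolerance (1e-4 on charge), the
H-bond cutoff (−0.5 kcal/mol), the contact threshold default (4.0 Å,
inclusive ≤) and the embedding retry budget (10) are all stated in the
function documentation and report metadata.
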