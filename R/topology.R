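# Heavy-atom topology of the 20 residues: PDB atom names and the bond
# graph (with formal bond orders consistent with the SMILES fragments).
# Backbone atoms N, CA, C, O are implicit in every residue; the side-chain
# tables below attach at CA (proline additionally closes its ring onto N).

sc_topo <- function(atoms, bonds) {
  list(atoms = atoms,
       bonds = if (is.null(bonds)) {
         data.frame(a = character(0), b = character(0), order = integer(0))
       } else {
         data.frame(a = vapply(bonds, `[`, character(1), 1),
                    b = vapply(bonds, `[`, character(1), 2),
                    order = as.integer(vapply(bonds, `[`, character(1), 3)),
                    stringsAsFactors = FALSE)
       })
}

SIDECHAIN_TOPO <- list(
  A = sc_topo("CB", list(c("CA", "CB", "1"))),
  R = sc_topo(c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"), c("CG", "CD", "1"),
                   c("CD", "NE", "1"), c("NE", "CZ", "2"),
                   c("CZ", "NH1", "1"), c("CZ", "NH2", "1"))),
  N = sc_topo(c("CB", "CG", "OD1", "ND2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "OD1", "2"), c("CG", "ND2", "1"))),
  D = sc_topo(c("CB", "CG", "OD1", "OD2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "OD1", "2"), c("CG", "OD2", "1"))),
  C = sc_topo(c("CB", "SG"),
              list(c("CA", "CB", "1"), c("CB", "SG", "1"))),
  E = sc_topo(c("CB", "CG", "CD", "OE1", "OE2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"), c("CG", "CD", "1"),
                   c("CD", "OE1", "2"), c("CD", "OE2", "1"))),
  Q = sc_topo(c("CB", "CG", "CD", "OE1", "NE2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"), c("CG", "CD", "1"),
                   c("CD", "OE1", "2"), c("CD", "NE2", "1"))),
  G = sc_topo(character(0), NULL),
  H = sc_topo(c("CB", "CG", "CD2", "NE2", "CE1", "ND1"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "CD2", "2"), c("CD2", "NE2", "1"),
                   c("NE2", "CE1", "2"), c("CE1", "ND1", "1"),
                   c("ND1", "CG", "1"))),
  I = sc_topo(c("CB", "CG1", "CG2", "CD1"),
              list(c("CA", "CB", "1"), c("CB", "CG1", "1"),
                   c("CB", "CG2", "1"), c("CG1", "CD1", "1"))),
  L = sc_topo(c("CB", "CG", "CD1", "CD2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "CD1", "1"), c("CG", "CD2", "1"))),
  K = sc_topo(c("CB", "CG", "CD", "CE", "NZ"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"), c("CG", "CD", "1"),
                   c("CD", "CE", "1"), c("CE", "NZ", "1"))),
  M = sc_topo(c("CB", "CG", "SD", "CE"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "SD", "1"), c("SD", "CE", "1"))),
  F = sc_topo(c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "CD1", "2"), c("CD1", "CE1", "1"),
                   c("CE1", "CZ", "2"), c("CZ", "CE2", "1"),
                   c("CE2", "CD2", "2"), c("CD2", "CG", "1"))),
  P = sc_topo(c("CB", "CG", "CD"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "CD", "1"), c("CD", "N", "1"))),
  S = sc_topo(c("CB", "OG"),
              list(c("CA", "CB", "1"), c("CB", "OG", "1"))),
  T = sc_topo(c("CB", "OG1", "CG2"),
              list(c("CA", "CB", "1"), c("CB", "OG1", "1"),
                   c("CB", "CG2", "1"))),
  W = sc_topo(c("CB", "CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ3",
                "CH2", "CZ2"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "CD1", "2"), c("CD1", "NE1", "1"),
                   c("NE1", "CE2", "1"), c("CE2", "CD2", "1"),
                   c("CD2", "CG", "1"), c("CE2", "CZ2", "2"),
                   c("CZ2", "CH2", "1"), c("CH2", "CZ3", "2"),
                   c("CZ3", "CE3", "1"), c("CE3", "CD2", "2"))),
  Y = sc_topo(c("CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH"),
              list(c("CA", "CB", "1"), c("CB", "CG", "1"),
                   c("CG", "CD1", "2"), c("CD1", "CE1", "1"),
                   c("CE1", "CZ", "2"), c("CZ", "CE2", "1"),
                   c("CE2", "CD2", "2"), c("CD2", "CG", "1"),
                   c("CZ", "OH", "1"))),
  V = sc_topo(c("CB", "CG1", "CG2"),
              list(c("CA", "CB", "1"), c("CB", "CG1", "1"),
                   c("CB", "CG2", "1")))
)

#' Heavy-atom molecular graph of a peptide
#'
#' Builds the full heavy-atom graph: per-residue backbone (N, CA, C, O)
#' plus side-chain atoms with PDB atom names, peptide bonds between
#' consecutive residues, and the C-terminal OXT.  Atom order is
#' N-terminus to C-terminus, backbone first within each residue.
#'
#' @param p a `peptide` or character sequence.
#' @return A list with `atoms` (data frame: name, element, resi, resn) and
#'   `bonds` (data frame: i, j atom indices, order).
#' @export
build_molecular_graph <- function(p) {
  p <- as_peptide(p)
  codes <- base_code(p$monomers)
  atoms <- NULL
  bonds <- NULL
  offset <- 0L
  prev_c <- NA_integer_
  for (ri in seq_along(codes)) {
    cd <- codes[ri]
    topo <- SIDECHAIN_TOPO[[cd]]
    names_r <- c("N", "CA", "C", "O", topo$atoms)
    el <- substr(names_r, 1, 1)
    atoms_r <- data.frame(name = names_r, element = el, resi = ri,
                          resn = unname(AA3[cd]), stringsAsFactors = FALSE)
    idx <- function(nm) offset + match(nm, names_r)
    b <- rbind(
      data.frame(i = idx("N"), j = idx("CA"), order = 1L),
      data.frame(i = idx("CA"), j = idx("C"), order = 1L),
      data.frame(i = idx("C"), j = idx("O"), order = 2L),
      if (nrow(topo$bonds)) {
        data.frame(i = idx(topo$bonds$a), j = idx(topo$bonds$b),
                   order = topo$bonds$order)
      }
    )
    if (!is.na(prev_c)) {
      b <- rbind(b, data.frame(i = prev_c, j = idx("N"), order = 1L))
    }
    prev_c <- idx("C")
    atoms <- rbind(atoms, atoms_r)
    bonds <- rbind(bonds, b)
    offset <- offset + nrow(atoms_r)
  }
  # free-acid terminus
  atoms <- rbind(atoms, data.frame(name = "OXT", element = "O",
                                   resi = length(codes),
                                   resn = unname(AA3[codes[length(codes)]]),
                                   stringsAsFactors = FALSE))
  bonds <- rbind(bonds, data.frame(i = prev_c, j = nrow(atoms), order = 1L))
  rownames(atoms) <- rownames(bonds) <- NULL
  list(atoms = atoms, bonds = bonds)
}
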