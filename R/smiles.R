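# Sequence -> SMILES construction.
#
# Residue units are emitted N-terminus to C-terminus, one unit per residue,
# so the atom order mirrors the backbone and the residue sequence is
# recoverable from the string.  Every unit is "N[C@@H](<side chain>)C(=O)"
# (glycine "NCC(=O)", proline closes its pyrrolidine ring onto the backbone
# N), the final unit gains the free-acid "O".  D-residues invert every
# stereo tag of their unit.

flip_stereo <- function(s) {
  s <- gsub("@@", "\001", s, fixed = TRUE)
  s <- gsub("@", "@@", s, fixed = TRUE)
  gsub("\001", "@", s, fixed = TRUE)
}

residue_unit <- function(code) {
  b <- base_code(code)
  unit <- if (b == "G") {
    "NCC(=O)"
  } else if (b == "P") {
    "N1CCC[C@H]1C(=O)"
  } else {
    paste0("N[C@@H](", SIDECHAIN_SMILES[[b]], ")C(=O)")
  }
  if (grepl("^d", code)) flip_stereo(unit) else unit
}

#' Peptide SMILES
#'
#' Builds the linear SMILES of a peptide with a free amine N-terminus and
#' free acid C-terminus.  Atoms are emitted N- to C-terminus so residue
#' order is recoverable by walking the backbone amides
#' (see [from_smiles()]).  All stereocenters carry chirality tags
#' (L default, inverted for D-residues).  Output is deterministic:
#' identical input gives a byte-identical string.
#'
#' @param p a `peptide` or character sequence.
#' @return character scalar SMILES.
#' @examples
#' to_smiles("G")   # "NCC(=O)O"
#' to_smiles("GG")
#' @export
to_smiles <- function(p) {
  p <- as_peptide(p)
  paste0(paste(vapply(p$monomers, residue_unit, character(1)), collapse = ""),
         "O")
}

#' Decode the residue sequence from a peptide SMILES
#'
#' Walks the backbone amide units of a SMILES produced by [to_smiles()]
#' and recovers the monomer sequence.  This is the inverse used by the
#' round-trip identity `from_smiles(to_smiles(p)) == p`.
#'
#' @param smiles character scalar.
#' @return A `peptide`.
#' @export
from_smiles <- function(smiles) {
  units <- unlist(lapply(monomer_table()$code, function(cd) {
    u <- residue_unit(cd)
    names(u) <- cd
    u
  }))
  units <- units[order(-nchar(units))]
  rest <- smiles
  monomers <- character(0)
  while (nchar(rest) > 1L) {
    hit <- NA_character_
    for (k in seq_along(units)) {
      if (startsWith(rest, units[[k]])) {
        hit <- names(units)[k]
        rest <- substr(rest, nchar(units[[k]]) + 1L, nchar(rest))
        break
      }
    }
    if (is.na(hit)) err_chemistry(sprintf("cannot decode SMILES at '%s'",
                                          substr(rest, 1, 20)))
    monomers <- c(monomers, hit)
  }
  if (!identical(rest, "O")) {
    err_chemistry("SMILES does not terminate in a free acid")
  }
  new_peptide(monomers)
}

#' Canonical SMILES via Open Babel
#'
#' Canonicalizes a SMILES string with the Open Babel toolkit, so two
#' representations of the same molecule compare equal.
#' @param smiles character scalar.
#' @return character scalar canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) err_chemistry(paste("SMILES parsing failed:",
                                            conditionMessage(e))))
  out <- sub("[\t\n].*$", "", out)
  if (!nzchar(out)) err_chemistry("SMILES could not be canonicalized")
  out
}
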