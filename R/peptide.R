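#' Parse a peptide sequence
#'
#' Validates a one-letter amino-acid string and returns a `peptide` object.
#' Lowercase single letters are normalized to uppercase L-residues;
#' D-amino acids must be written with the bracketed token convention,
#' e.g. `"A[dA]G"` for Ala, D-Ala, Gly.  Any character outside the
#' registered monomer table is rejected with the offending residue
#' position.
#'
#' @param text character scalar, the sequence.  Surrounding whitespace is
#'   stripped.
#' @param cyclic logical, head-to-tail cyclic topology flag.  It affects
#'   interaction-graph layout and HELM rendering only; SMILES output is
#'   always the linear peptide.
#' @return An object of class `peptide`: an ordered set of monomer codes
#'   with a `length()`, `print()` and `as.character()` method.
#' @examples
#' parse_sequence("GAVL")
#' parse_sequence("A[dA]G")
#' @export
parse_sequence <- function(text, cyclic = FALSE) {
  if (length(text) != 1L || !is.character(text)) {
    err_domain("sequence must be a single character string")
  }
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) err_empty_sequence()

  known <- monomer_table()$code
  chars <- strsplit(text, "")[[1]]
  monomers <- character(0)
  i <- 1L
  pos <- 0L
  while (i <= length(chars)) {
    pos <- pos + 1L
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]")
      close <- close[close > i][1]
      if (is.na(close)) err_invalid_monomer(substr(text, i, nchar(text)), pos)
      token <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!(token %in% known)) err_invalid_monomer(paste0("[", token, "]"), pos)
      monomers <- c(monomers, token)
      i <- close + 1L
    } else {
      token <- toupper(ch)
      if (!(token %in% AA1)) err_invalid_monomer(ch, pos)
      monomers <- c(monomers, token)
      i <- i + 1L
    }
  }
  new_peptide(monomers, cyclic)
}

new_peptide <- function(monomers, cyclic = FALSE) {
  structure(list(monomers = monomers, is_cyclic = isTRUE(cyclic)),
            class = "peptide")
}

#' Coerce to a peptide
#'
#' Character input is parsed with [parse_sequence()]; `peptide` objects pass
#' through unchanged.
#' @param x a `peptide` or character scalar.
#' @return A `peptide`.
#' @export
as_peptide <- function(x) {
  if (inherits(x, "peptide")) return(x)
  parse_sequence(x)
}

#' @export
length.peptide <- function(x) length(x$monomers)

#' Render a peptide back to its sequence string
#'
#' The canonical rendering: one-letter codes for L-residues, bracketed
#' `[dX]` tokens for D-residues.  `parse_sequence(as.character(p))`
#' reproduces `p`.
#' @param x a `peptide`.
#' @param ... unused.
#' @export
as.character.peptide <- function(x, ...) {
  paste(ifelse(grepl("^d", x$monomers),
               paste0("[", x$monomers, "]"),
               x$monomers),
        collapse = "")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s (%d residues%s)\n",
              as.character(x), length(x),
              if (x$is_cyclic) ", cyclic" else ""))
  invisible(x)
}

#' @export
`==.peptide` <- function(e1, e2) {
  identical(e1$monomers, e2$monomers) && e1$is_cyclic == e2$is_cyclic
}

#' HELM notation
#'
#' Renders the peptide as a HELM v2 simple-polymer string
#' (`PEPTIDE1{A.G}$$$$`).  Multi-character monomer IDs (the D-amino acid
#' tokens) are bracketed per the HELM grammar.  Cyclic peptides add a
#' head-to-tail connection in the HELM connection section.
#'
#' @param p a `peptide` or character sequence.
#' @return character scalar, the HELM string.
#' @examples
#' to_helm("A[dA]G")
#' @export
to_helm <- function(p) {
  p <- as_peptide(p)
  ids <- ifelse(nchar(p$monomers) > 1L,
                paste0("[", p$monomers, "]"),
                p$monomers)
  body <- paste(ids, collapse = ".")
  conn <- if (p$is_cyclic) {
    sprintf("PEPTIDE1,PEPTIDE1,%d:R2-1:R1", length(p))
  } else ""
  sprintf("PEPTIDE1{%s}$%s$$$", body, conn)
}

#' Parse a HELM simple-polymer string
#'
#' Inverse of [to_helm()] for single-peptide HELM strings.
#' @param helm character scalar.
#' @return A `peptide`.
#' @export
from_helm <- function(helm) {
  m <- regmatches(helm, regexec("^PEPTIDE1\\{([^}]+)\\}\\$([^$]*)\\$", helm))[[1]]
  if (length(m) < 2L) err_domain("not a recognised HELM simple-polymer string")
  tokens <- strsplit(m[2], ".", fixed = TRUE)[[1]]
  tokens <- gsub("^\\[|\\]$", "", tokens)
  known <- monomer_table()$code
  bad <- which(!(tokens %in% known))
  if (length(bad)) err_invalid_monomer(tokens[bad[1]], bad[1])
  cyclic <- length(m) >= 3L && grepl("R2-1:R1", m[3])
  new_peptide(tokens, cyclic)
}
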