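# Gap-free, position-by-position peptide alignment.
#
# Peptides compared as ligands rather than evolutionary homologues: no gap
# opening, the score is the plain sum of substitution-matrix lookups at
# each position.  Unequal lengths are an error, never truncated.

#' Read a substitution matrix in NCBI text layout
#'
#' Parses the standard NCBI matrix format ('#' comments, a header row of
#' alphabet letters, one row per letter).  A BLOSUM62 copy ships with the
#' package: `system.file("extdata", "BLOSUM62.txt", package = "peptools")`.
#'
#' @param path file path.
#' @param name matrix name stored in the `"name"` attribute (defaults to
#'   the file base name).
#' @return A symmetric numeric matrix with the alphabet as dimnames.
#' @export
read_substitution_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) err_io(sprintf("matrix file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  letters_ <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(letters_, header)
  m <- vals[header, header, drop = FALSE]
  if (!isTRUE(all.equal(m, t(m)))) err_domain("substitution matrix is not symmetric")
  attr(m, "name") <- if (is.null(name)) {
    sub("\\.[^.]*$", "", basename(path))
  } else name
  m
}

#' Built-in BLOSUM62
#'
#' Loads the BLOSUM62 matrix shipped with the package.
#' @return A substitution matrix (see [read_substitution_matrix()]).
#' @export
blosum62 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "peptools"),
    name = "BLOSUM62")
}

#' Position-by-position peptide alignment
#'
#' Scores two equal-length peptides with no gaps: the alignment score is
#' the exact sum of `m[a_i, b_i]` over positions.  A pair is "identical"
#' when the residues match and "similar" when its matrix score is strictly
#' positive.  D-residues are scored by their parent one-letter code.
#'
#' @param a,b `peptide` objects or character sequences of equal length.
#' @param m substitution matrix (default [blosum62()]).
#' @return An object of class `alignment_result` with `score`,
#'   `per_position` (residue pair, score, identity flag per position),
#'   `n_identical` and `n_similar`.
#' @examples
#' align_positionwise("AAAA", "AAAA")
#' @export
align_positionwise <- function(a, b, m = blosum62()) {
  a <- as_peptide(a); b <- as_peptide(b)
  if (length(a) != length(b)) {
    err_length_mismatch(sprintf(
      "gap-free alignment requires equal lengths (%d vs %d)",
      length(a), length(b)))
  }
  ra <- base_code(a$monomers)
  rb <- base_code(b$monomers)
  alpha <- rownames(m)
  bad <- setdiff(unique(c(ra, rb)), alpha)
  if (length(bad)) {
    err_alphabet(sprintf("residue(s) %s not in matrix alphabet",
                         paste(bad, collapse = ", ")))
  }
  scores <- m[cbind(ra, rb)]
  per <- data.frame(residue_a = ra, residue_b = rb, score = scores,
                    is_identity = ra == rb, stringsAsFactors = FALSE)
  structure(list(score = sum(scores),
                 per_position = per,
                 n_identical = sum(per$is_identity),
                 n_similar = sum(scores > 0),
                 matrix_name = attr(m, "name")),
            class = "alignment_result")
}

#' Fraction of similar positions
#'
#' `n_similar / length`: the fraction of positions whose substitution score
#' is strictly positive.  Always in `[0, 1]`.
#' @param r an `alignment_result`.
#' @return numeric scalar.
#' @export
similarity_fraction <- function(r) {
  stopifnot(inherits(r, "alignment_result"))
  r$n_similar / nrow(r$per_position)
}

#' @export
print.alignment_result <- function(x, ...) {
  n <- nrow(x$per_position)
  cat(sprintf("<alignment_result> %s vs %s  [%s]\n",
              paste(x$per_position$residue_a, collapse = ""),
              paste(x$per_position$residue_b, collapse = ""),
              x$matrix_name %||% "matrix"))
  cat(sprintf("  score %g, %d/%d identical, %d/%d similar\n",
              x$score, x$n_identical, n, x$n_similar, n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format an offline blastp query (stub)
#'
#' Network submission of peptide queries is out of scope; this helper only
#' formats the FASTA query record and the parameter set tuned for short
#' peptide searches, for use with an external BLAST client.
#'
#' @param p a `peptide` or character sequence.
#' @param id record identifier.
#' @return A list with the FASTA `query` text and suggested `parameters`.
#' @export
format_blast_query <- function(p, id = "peptide_query") {
  p <- as_peptide(p)
  list(query = sprintf(">%s\n%s\n", id, as.character(p)),
       parameters = list(program = "blastp", task = "blastp-short",
                         word_size = 2, expect = 20000,
                         matrix = "PAM30", gapopen = 9, gapextend = 1))
}
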