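# Combinatorial peptide library design: pattern expansion, single-position
# scans, frequency-driven sampling, and the frequency-matrix summary
# behind sequence-logo plots.

MAX_EXHAUSTIVE <- 1e7

lib_alphabet <- function(include_d = FALSE) {
  if (include_d) c(AA1, paste0("d", AA1)) else AA1
}

#' Expand a sequence pattern into a library
#'
#' Expands a pattern such as `"XRTEX"`, where `X` stands for any residue
#' of the alphabet and any other letter is fixed, into the exact Cartesian
#' set of matching sequences.  Output is deduplicated and
#' lexicographically sorted.  Expansions beyond 10^7 sequences are
#' refused; use [sample_library()] for such designs.
#'
#' @param pattern character scalar; `X` = any alphabet residue.
#' @param alphabet residue alphabet (default the 20 canonical L-residues).
#' @return Character vector of sequences.
#' @examples
#' length(expand_pattern("XRTEX"))  # 400
#' @export
expand_pattern <- function(pattern, alphabet = lib_alphabet()) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern)) {
    err_pattern("pattern must be a non-empty string")
  }
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(unique(chars), c(alphabet, "X"))
  if (length(bad)) {
    err_pattern(sprintf("pattern character(s) %s not in alphabet",
                        paste(sQuote(bad), collapse = ", ")))
  }
  n_x <- sum(chars == "X")
  if (length(alphabet)^n_x > MAX_EXHAUSTIVE) {
    err_pattern(sprintf(
      "expansion of %d free positions over %d residues exceeds %g sequences; use sample_library()",
      n_x, length(alphabet), MAX_EXHAUSTIVE))
  }
  bracket <- function(x) ifelse(nchar(x) > 1L, paste0("[", x, "]"), x)
  slots <- lapply(chars, function(ch) {
    if (ch == "X") bracket(alphabet) else bracket(ch)
  })
  grid <- do.call(expand.grid, c(rev(slots), stringsAsFactors = FALSE))
  seqs <- do.call(paste0, rev(grid))
  sort(unique(seqs))
}

#' Single-position scan library
#'
#' Every single-position substitution of the base sequence by every
#' alphabet residue (the base itself kept once after deduplication), so
#' the pooled set shows a uniform representation of each residue at each
#' position.
#'
#' @param base a `peptide` or character sequence.
#' @param alphabet residue alphabet.
#' @return Character vector of unique sequences, sorted.
#' @examples
#' length(scan_library("AAA"))  # 58
#' @export
scan_library <- function(base, alphabet = lib_alphabet()) {
  base <- as_peptide(base)
  codes <- base$monomers
  out <- unlist(lapply(seq_along(codes), function(i) {
    vapply(alphabet, function(a) {
      s <- codes
      s[i] <- a
      as.character(new_peptide(s))
    }, character(1))
  }))
  sort(unique(out))
}

#' Sample a peptide library from per-position frequencies
#'
#' Draws `n` sequences with independent per-position residue
#' distributions.  `frequencies` may be a positions-by-alphabet matrix of
#' probabilities (rows summing to 1) or `NULL` for the uniform library of
#' the given `length`.  Sampling is reproducible for a fixed seed.
#'
#' @param n number of sequences.
#' @param length peptide length (when `frequencies` is `NULL`).
#' @param frequencies optional positions x alphabet probability matrix
#'   with alphabet column names.
#' @param seed integer random seed.
#' @param alphabet residue alphabet (ignored when `frequencies` has
#'   column names).
#' @return Character vector of `n` sequences.
#' @export
sample_library <- function(n, length = NULL, frequencies = NULL, seed = 1L,
                           alphabet = lib_alphabet()) {
  if (!is.numeric(n) || n < 1) err_domain("sample size must be >= 1")
  if (is.null(frequencies)) {
    if (is.null(length)) err_domain("provide a length or a frequency matrix")
    frequencies <- matrix(1 / base::length(alphabet),
                          nrow = length, ncol = base::length(alphabet),
                          dimnames = list(NULL, alphabet))
  }
  if (is.null(colnames(frequencies))) colnames(frequencies) <- alphabet
  bad <- which(rowSums(frequencies) <= 0)
  if (base::length(bad)) {
    err_frequency(sprintf("degenerate frequency row at position %d", bad[1]))
  }
  if (any(abs(rowSums(frequencies) - 1) > 1e-9)) {
    err_frequency("frequency rows must sum to 1")
  }
  set.seed(as.integer(seed))
  ab <- colnames(frequencies)
  draws <- vapply(seq_len(nrow(frequencies)), function(pos) {
    sample(ab, n, replace = TRUE, prob = frequencies[pos, ])
  }, character(n))
  draws <- matrix(draws, nrow = n)
  apply(draws, 1, function(row) as.character(new_peptide(row)))
}

#' Per-position residue frequency matrix
#'
#' Observed residue fractions at every position of an equal-length
#' sequence set: the data behind a sequence logo.
#'
#' @param sequences character vector of equal-length sequences (bracketed
#'   D-tokens allowed).
#' @param alphabet residue alphabet for the columns.
#' @return Numeric matrix, positions x alphabet; rows sum to 1.
#' @export
frequency_matrix <- function(sequences, alphabet = lib_alphabet()) {
  peps <- lapply(sequences, as_peptide)
  lens <- vapply(peps, length, integer(1))
  if (length(unique(lens)) > 1L) {
    err_length_mismatch("sequences must all have the same length")
  }
  L <- lens[1]
  m <- matrix(0, nrow = L, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  for (p in peps) {
    for (i in seq_len(L)) {
      m[i, p$monomers[i]] <- m[i, p$monomers[i]] + 1
    }
  }
  m / length(peps)
}

#' Write a library to disk
#'
#' Writes sequences as a plain list (one per line), FASTA, or HELM (one
#' HELM string per line, D-tokens bracketed).
#'
#' @param sequences character vector of sequences.
#' @param path output path.
#' @param format `"list"`, `"fasta"` or `"helm"`.
#' @return The path, invisibly.
#' @export
write_library <- function(sequences, path, format = c("list", "fasta", "helm")) {
  format <- match.arg(format)
  lines <- switch(format,
    list = sequences,
    fasta = as.vector(rbind(sprintf(">seq_%05d", seq_along(sequences)),
                            sequences)),
    helm = vapply(sequences, function(s) to_helm(s), character(1),
                  USE.NAMES = FALSE))
  writeLines(lines, path)
  invisible(path)
}
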