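# Classed error conditions so callers can branch on failure modes
# (testthat uses expect_error(class = ...)).

pep_stop <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(subclass, "peptools_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

#' @noRd
err_empty_sequence <- function(msg = "empty sequence") {
  pep_stop("pep_empty_sequence", msg)
}

err_invalid_monomer <- function(token, position) {
  pep_stop("pep_invalid_monomer",
           sprintf("invalid monomer '%s' at position %d", token, position),
           token = token, position = position)
}

err_domain <- function(msg) pep_stop("pep_domain_error", msg)
err_chemistry <- function(msg) pep_stop("pep_chemistry_error", msg)
err_length_mismatch <- function(msg) pep_stop("pep_length_mismatch", msg)
err_alphabet <- function(msg) pep_stop("pep_alphabet_error", msg)
err_chain_not_found <- function(msg) pep_stop("pep_chain_not_found", msg)
err_empty_structure <- function(msg) pep_stop("pep_empty_structure", msg)
err_pattern <- function(msg) pep_stop("pep_pattern_error", msg)
err_frequency <- function(msg) pep_stop("pep_frequency_error", msg)
err_embedding <- function(msg) pep_stop("pep_embedding_error", msg)
err_annotation <- function(msg) pep_stop("pep_annotation_error", msg)
err_dependency <- function(msg) pep_stop("pep_dependency_error", msg)
err_io <- function(msg) pep_stop("pep_io_error", msg)
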