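# Empirical solubility and synthesis rules.
#
# Registered rule set v1.  The two composition/charge solubility rules and
# the charge rule follow the published empirical guidance (charged or
# hydrophobic content exceeding 45% of the sequence, absolute net charge at
# pH 7 above 1); the synthesis rules are the common sequence liabilities
# screened in peptide synthesis practice.  All thresholds are strict
# inequalities ("exceeds" / "more than"), so a sequence at exactly 45%
# charged content passes.

rule_registry <- function() {
  list(
    list(id = "R-S1", category = "solubility",
         statement = "fraction of charged residues (D,E,K,R,H) exceeds 45%",
         check = function(p) {
           frac <- mean(base_code(p$monomers) %in% CHARGED_SET)
           list(failed = frac > 0.45, evidence = sprintf("charged fraction %.3f", frac))
         }),
    list(id = "R-S2", category = "solubility",
         statement = "fraction of hydrophobic residues (A,I,L,M,F,W,V,Y) exceeds 45%",
         check = function(p) {
           frac <- mean(base_code(p$monomers) %in% HYDROPHOBIC_SET)
           list(failed = frac > 0.45, evidence = sprintf("hydrophobic fraction %.3f", frac))
         }),
    list(id = "R-S3", category = "solubility",
         statement = "absolute net charge at pH 7 is more than 1",
         check = function(p) {
           q <- net_charge(p, 7.0)
           list(failed = abs(q) > 1, evidence = sprintf("net charge %+.3f", q))
         }),
    list(id = "R-X1", category = "synthesis",
         statement = "4 or more identical consecutive residues",
         check = function(p) {
           s <- paste(base_code(p$monomers), collapse = "")
           m <- regmatches(s, regexpr("([A-Z])\\1{3,}", s))
           list(failed = length(m) > 0,
                evidence = if (length(m)) sprintf("run '%s'", m) else "no run of 4")
         }),
    list(id = "R-X2", category = "synthesis",
         statement = "aspartate-mediated cleavage motif DG or DP present",
         check = function(p) {
           s <- paste(base_code(p$monomers), collapse = "")
           m <- regmatches(s, regexpr("D[GP]", s))
           list(failed = length(m) > 0,
                evidence = if (length(m)) sprintf("motif '%s'", m) else "no DG/DP")
         }),
    list(id = "R-X3", category = "synthesis",
         statement = "N-terminal Gln or Asn (cyclization/deamidation risk)",
         check = function(p) {
           first <- base_code(p$monomers)[1]
           list(failed = first %in% c("Q", "N"),
                evidence = sprintf("N-terminal residue %s", first))
         }),
    list(id = "R-X4", category = "synthesis",
         statement = "more than 75% of 5-residue windows lack a charged residue",
         check = function(p) {
           codes <- base_code(p$monomers)
           n <- length(codes)
           w <- min(5L, n)
           starts <- seq_len(n - w + 1L)
           uncharged <- vapply(starts, function(i) {
             !any(codes[i:(i + w - 1L)] %in% CHARGED_SET)
           }, logical(1))
           frac <- mean(uncharged)
           list(failed = frac > 0.75,
                evidence = sprintf("%.0f%% of %d windows uncharged",
                                   100 * frac, length(starts)))
         }),
    list(id = "R-X5", category = "synthesis",
         statement = "2 or more oxidation-prone residues (M, C, W combined)",
         check = function(p) {
           cnt <- sum(base_code(p$monomers) %in% c("M", "C", "W"))
           list(failed = cnt >= 2, evidence = sprintf("%d oxidation-prone residues", cnt))
         })
  )
}

check_rules <- function(p, category) {
  p <- as_peptide(p)
  rules <- Filter(function(r) r$category == category, rule_registry())
  rows <- lapply(rules, function(r) {
    res <- r$check(p)
    data.frame(rule = r$id, category = r$category, statement = r$statement,
               failed = res$failed, evidence = res$evidence,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  structure(rep, n_failed = sum(rep$failed), class = c("rule_report", "data.frame"))
}

#' Empirical solubility rules
#'
#' Evaluates the registered solubility rules: charged fraction > 45%,
#' hydrophobic fraction > 45%, and absolute net charge at pH 7 above 1.
#' More failed rules indicate a lower chance of solubilizing the peptide.
#'
#' @param p a `peptide` or character sequence.
#' @return A `rule_report` data frame (one row per rule: id, statement,
#'   failed flag, evidence) with attribute `n_failed`.
#' @examples
#' check_solubility_rules("KKKKK")
#' @export
check_solubility_rules <- function(p) check_rules(p, "solubility")

#' Empirical synthesis rules
#'
#' Evaluates the registered synthesis-liability rules: runs of 4+ identical
#' residues, DG/DP cleavage motifs, N-terminal Gln/Asn, predominantly
#' uncharged 5-residue windows, and 2+ oxidation-prone residues (Met, Cys,
#' Trp).  More failed rules indicate a harder synthesis.
#'
#' @inheritParams check_solubility_rules
#' @return A `rule_report` data frame with attribute `n_failed`.
#' @examples
#' check_synthesis_rules("AAAAG")
#' @export
check_synthesis_rules <- function(p) check_rules(p, "synthesis")

#' @export
print.rule_report <- function(x, ...) {
  cat(sprintf("<rule_report> %d of %d rules failed\n",
              attr(x, "n_failed"), nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-4s %s  (%s)\n",
                if (x$failed[i]) "FAIL" else " ok ",
                x$rule[i], x$statement[i], x$evidence[i]))
  }
  invisible(x)
}

#' Serialize rule reports to JSON
#'
#' @param x a `rule_report`.
#' @return character scalar JSON.
#' @export
rule_report_json <- function(x) {
  jsonlite::toJSON(list(rules = as.data.frame(x),
                        n_failed = attr(x, "n_failed")),
                   auto_unbox = TRUE, pretty = TRUE)
}
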