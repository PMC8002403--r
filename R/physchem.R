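# Sequence- and SMILES-derived physico-chemical descriptors.

ionizable_groups <- function(p) {
  p <- as_peptide(p)
  codes <- base_code(p$monomers)
  side <- codes[codes %in% names(AA_PKA)]
  data.frame(
    group = c("nterm", "cterm", side),
    pka = c(PKA_NTERM, PKA_CTERM, unname(AA_PKA[side])),
    sign = c(+1, -1, unname(AA_PKA_SIGN[side]))
  )
}

#' Henderson-Hasselbalch net charge
#'
#' Net peptide charge at a given pH: partial charges of every ionizable
#' side chain plus the free N- and C-termini, summed.  A basic group
#' contributes `+1 / (1 + 10^(pH - pKa))`, an acidic group
#' `-1 / (1 + 10^(pKa - pH))`.  Side-chain pKa values are the pinned
#' Lehninger set; termini use pKa 9.0 (amino) and 2.0 (carboxyl).
#'
#' @param p a `peptide` or character sequence.
#' @param pH numeric in `[0, 14]`.
#' @return numeric scalar, the net charge (dimensionless).
#' @examples
#' net_charge("EEE", 7)    # about -3
#' net_charge("KKKKK", 7)  # about +5
#' @export
net_charge <- function(p, pH = 7.0) {
  if (!is.numeric(pH) || length(pH) != 1L || is.na(pH) || pH < 0 || pH > 14) {
    err_domain("pH must be a single value in [0, 14]")
  }
  g <- ionizable_groups(p)
  basic <- g$sign > 0
  sum(ifelse(basic,
             1 / (1 + 10^(pH - g$pka)),
             -1 / (1 + 10^(g$pka - pH))))
}

#' Eisenberg hydrophobicity score
#'
#' Sum of the Eisenberg consensus hydrophobicity values over all residues.
#' The aggregate is a sum, not a mean, so the score is additive over
#' concatenation and grows with peptide length.
#'
#' @param p a `peptide` or character sequence.
#' @return numeric scalar (scale units).
#' @export
hydrophobicity <- function(p) {
  p <- as_peptide(p)
  sum(EISENBERG[base_code(p$monomers)])
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge vanishes, found by
#' bisection on `[0, 14]` (at most `max_iter` halvings, stopping when
#' `|charge| < tol`).  The result is self-consistent with [net_charge()]
#' by construction.
#'
#' @param p a `peptide` or character sequence.
#' @param tol convergence tolerance on the absolute charge.
#' @param max_iter maximum bisection iterations.
#' @return numeric scalar in (0, 14), pH units.
#' @export
isoelectric_point <- function(p, tol = 1e-4, max_iter = 64L) {
  p <- as_peptide(p)
  lo <- 0; hi <- 14
  # charge is monotone non-increasing in pH: positive at 0, negative at 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    q <- net_charge(p, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' ProtParam-style sequence properties
#'
#' Aromaticity (fraction of Phe/Trp/Tyr), the Guruprasad instability index
#' `(10/L) * sum(DIWV(x_i, x_{i+1}))` over consecutive dipeptides, and the
#' isoelectric point (see [isoelectric_point()]).  The instability index is
#' undefined for single residues: a warning is raised and `NA` returned for
#' that field only.
#'
#' @param p a `peptide` or character sequence.
#' @return A list with `aromaticity`, `instability_index`,
#'   `isoelectric_point`.
#' @export
protparam_properties <- function(p) {
  p <- as_peptide(p)
  codes <- base_code(p$monomers)
  n <- length(codes)
  arom <- mean(codes %in% AROMATIC_SET)
  if (n < 2L) {
    warning("instability index is undefined for single-residue peptides")
    inst <- NA_real_
  } else {
    inst <- 10 / n * sum(DIWV[cbind(codes[-n], codes[-1])])
  }
  list(aromaticity = arom,
       instability_index = inst,
       isoelectric_point = isoelectric_point(p))
}

ob_with_mol <- function(smiles, fn) {
  res <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, fn)),
    error = function(e) err_chemistry(paste("SMILES parsing failed:",
                                            conditionMessage(e))))
  res[[1]]
}

#' SMILES-derived descriptors
#'
#' Computes, from a SMILES string via the Open Babel toolkit:
#' average molecular weight (implicit hydrogens included), the
#' Wildman-Crippen atom-contribution logP, and Lipinski-convention
#' hydrogen-bond donor/acceptor counts.  The donor/acceptor convention is
#' the SMARTS pair recorded in the result: donors are N/O atoms bearing at
#' least one hydrogen (`[#7,#8;!H0]`), acceptors are all N/O atoms
#' (`[#7,#8]`).
#'
#' @param smiles character scalar, a parseable SMILES.
#' @return A list with `molecular_weight` (g/mol), `crippen_logp`,
#'   `n_hbond_donors`, `n_hbond_acceptors`, and `convention`.
#' @examples
#' \donttest{smiles_descriptors(to_smiles("G"))}
#' @export
smiles_descriptors <- function(smiles) {
  donors_smarts <- "[#7,#8;!H0]"
  acceptors_smarts <- "[#7,#8]"
  out <- ob_with_mol(smiles, function(mol) {
    pr <- ChemmineOB::prop_OB(mol)
    list(mw = pr$MW, logp = pr$logP,
         don = as.integer(ChemmineOB::smartsSearch_OB(
           list(mol), donors_smarts, uniqueMatches = TRUE)),
         acc = as.integer(ChemmineOB::smartsSearch_OB(
           list(mol), acceptors_smarts, uniqueMatches = TRUE)))
  })
  list(molecular_weight = out$mw,
       crippen_logp = out$logp,
       n_hbond_donors = out$don,
       n_hbond_acceptors = out$acc,
       convention = c(donors = donors_smarts, acceptors = acceptors_smarts))
}

#' Full per-peptide property report
#'
#' Computes the complete descriptor roster for one peptide: net charge at
#' the stated pH, SMILES-derived molecular weight, Wildman-Crippen logP and
#' hydrogen-bond donor/acceptor counts, summed Eisenberg hydrophobicity,
#' aromaticity, instability index, isoelectric point, and the number of
#' failed empirical solubility and synthesis rules.
#'
#' @param p a `peptide` or character sequence.
#' @param pH pH for the net-charge field (default 7).
#' @return An object of class `property_report` (a named list).
#' @examples
#' \donttest{property_report("GAVLKKDE")}
#' @export
property_report <- function(p, pH = 7.0) {
  p <- as_peptide(p)
  sm <- to_smiles(p)
  pp <- protparam_properties(p)
  sd <- smiles_descriptors(sm)
  sol <- check_solubility_rules(p)
  syn <- check_synthesis_rules(p)
  structure(list(
    sequence = as.character(p),
    length = length(p),
    net_charge = net_charge(p, pH),
    pH = pH,
    molecular_weight = sd$molecular_weight,
    crippen_logp = sd$crippen_logp,
    hydrophobicity_eisenberg = hydrophobicity(p),
    aromaticity = pp$aromaticity,
    instability_index = pp$instability_index,
    isoelectric_point = pp$isoelectric_point,
    n_hbond_donors = sd$n_hbond_donors,
    n_hbond_acceptors = sd$n_hbond_acceptors,
    n_solubility_rules_failed = attr(sol, "n_failed"),
    n_synthesis_rules_failed = attr(syn, "n_failed"),
    smiles = sm,
    hbond_convention = sd$convention
  ), class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat(sprintf("<property_report> %s (%d residues)\n", x$sequence, x$length))
  num <- function(v) formatC(v, digits = 3, format = "f")
  cat(sprintf("  net charge (pH %.1f):  %s\n", x$pH, num(x$net_charge)))
  cat(sprintf("  molecular weight:     %s g/mol\n", num(x$molecular_weight)))
  cat(sprintf("  Crippen logP:         %s\n", num(x$crippen_logp)))
  cat(sprintf("  hydrophobicity (sum): %s\n", num(x$hydrophobicity_eisenberg)))
  cat(sprintf("  aromaticity:          %s\n", num(x$aromaticity)))
  cat(sprintf("  instability index:    %s\n", num(x$instability_index)))
  cat(sprintf("  isoelectric point:    %s\n", num(x$isoelectric_point)))
  cat(sprintf("  H-bond donors/acceptors: %d / %d\n",
              x$n_hbond_donors, x$n_hbond_acceptors))
  cat(sprintf("  rules failed: %d solubility, %d synthesis\n",
              x$n_solubility_rules_failed, x$n_synthesis_rules_failed))
  invisible(x)
}
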