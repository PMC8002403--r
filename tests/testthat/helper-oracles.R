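# Independent oracles and fixture helpers shared across the suite.
# Each oracle re-derives its quantity from first principles, separately
# from the implementation path it checks.

AA20 <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]

random_sequence <- function(len) paste(sample(AA20, len, replace = TRUE),
                                       collapse = "")

# --- Henderson-Hasselbalch oracle (own literal pKa copy) ----------------
ORACLE_PKA <- list(
  acidic = c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07, cterm = 2.0),
  basic  = c(H = 6.00, K = 10.53, R = 12.48, nterm = 9.0)
)

hh_oracle <- function(seq, pH) {
  aa <- strsplit(seq, "")[[1]]
  q <- 1 / (1 + 10^(pH - ORACLE_PKA$basic[["nterm"]])) -
       1 / (1 + 10^(ORACLE_PKA$acidic[["cterm"]] - pH))
  for (a in aa) {
    if (a %in% names(ORACLE_PKA$basic)) {
      q <- q + 1 / (1 + 10^(pH - ORACLE_PKA$basic[[a]]))
    } else if (a %in% names(ORACLE_PKA$acidic)) {
      q <- q - 1 / (1 + 10^(ORACLE_PKA$acidic[[a]] - pH))
    }
  }
  q
}

# --- alignment oracle: plain loop over positions ------------------------
align_oracle <- function(a, b, m) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  s <- 0
  for (i in seq_along(va)) s <- s + m[va[i], vb[i]]
  s
}

# --- contact oracle: O(N*M) double loop ---------------------------------
contact_oracle <- function(model, threshold) {
  a <- model$atoms[model$atoms$element != "H", ]
  pep <- a[a$role == "peptide", ]
  pro <- a[a$role == "protein", ]
  res <- sort(unique(pep$resno))
  counts <- integer(length(res))
  for (k in seq_along(res)) {
    ra <- pep[pep$resno == res[k], ]
    n <- 0L
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(pro))) {
      d <- sqrt((ra$x[i] - pro$x[j])^2 + (ra$y[i] - pro$y[j])^2 +
                (ra$z[i] - pro$z[j])^2)
      if (d <= threshold) n <- n + 1L
    }
    counts[k] <- n
  }
  counts
}

# random protein-peptide atom cloud written as a PDB (for contact tests)
random_cloud_complex <- function(seed, n_pro = 60, n_pep = 15) {
  set.seed(seed)
  n <- n_pro + n_pep
  xyz <- matrix(stats::runif(3 * n, 0, 18), ncol = 3)
  path <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = c(rep(1:6, length.out = n_pro),
                             rep(1:3, length.out = n_pep)),
                   resid = rep("GLY", n),
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = c(rep("A", n_pro), rep("C", n_pep)),
                   elesy = rep("C", n))
  path
}

# --- hydrogen donor/acceptor composition oracle -------------------------
# N/O atom counts per side chain: total and H-bearing, from the residue
# structures (neutral forms, guanidine tautomer with two NH2 groups,
# imidazole with one ring NH).
SC_NO <- list(
  A = c(0, 0), G = c(0, 0), V = c(0, 0), L = c(0, 0), I = c(0, 0),
  P = c(0, 0), F = c(0, 0), M = c(0, 0), C = c(0, 0),
  S = c(1, 1), T = c(1, 1), Y = c(1, 1), W = c(1, 1),
  D = c(2, 1), E = c(2, 1), N = c(2, 1), Q = c(2, 1),
  H = c(2, 1), K = c(1, 1), R = c(3, 2)
)

donor_acceptor_oracle <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  sc <- sapply(aa, function(a) SC_NO[[a]])
  # backbone: one amide N and one carbonyl O per residue, plus OXT
  acceptors <- 2L * length(aa) + 1L + sum(sc[1, ])
  # donors: every backbone N except internal prolines, plus the C-term OH
  internal_pro <- sum(aa[-1] == "P")
  donors <- length(aa) - internal_pro + 1L + sum(sc[2, ])
  c(donors = donors, acceptors = acceptors)
}
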