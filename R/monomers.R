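# Monomer table: the single source of truth for per-residue constants.
#
# Pinned sources:
#   * average molecular masses of the free amino acids (IUPAC atomic weights)
#   * side-chain pKa values from the Lehninger table; termini pKa fixed at
#     9.0 (alpha-amino) and 2.0 (alpha-carboxyl)
#   * Eisenberg consensus hydrophobicity scale
#   * category flags: charged = D,E,K,R,H; hydrophobic = A,I,L,M,F,W,V,Y;
#     aromatic = F,W,Y
# D-amino acids (codes "dA".."dY") share every scalar constant with their
# L-counterpart and differ only in stereochemistry.

AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# average mass of the free amino acid, g/mol
AA_MASS <- c(A = 89.094, R = 174.203, N = 132.119, D = 133.103, C = 121.158,
             E = 147.130, Q = 146.146, G = 75.067, H = 155.156, I = 131.175,
             L = 131.175, K = 146.189, M = 149.208, F = 165.192, P = 115.132,
             S = 105.093, T = 119.120, W = 204.229, Y = 181.191, V = 117.148)

# side-chain pKa (Lehninger) and the sign of the protonated form
AA_PKA <- c(D = 3.65, E = 4.25, C = 8.18, Y = 10.07,
            H = 6.00, K = 10.53, R = 12.48)
AA_PKA_SIGN <- c(D = -1, E = -1, C = -1, Y = -1, H = +1, K = +1, R = +1)

PKA_NTERM <- 9.0
PKA_CTERM <- 2.0

# Eisenberg consensus hydrophobicity
EISENBERG <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
               E = -0.74, Q = -0.85, G = 0.48, H = -0.40, I = 1.38,
               L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
               S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

CHARGED_SET <- c("D", "E", "K", "R", "H")
HYDROPHOBIC_SET <- c("A", "I", "L", "M", "F", "W", "V", "Y")
AROMATIC_SET <- c("F", "W", "Y")

# Guruprasad dipeptide instability weight values (DIWV); rows = first
# residue of the dipeptide, cols = second.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

# Theoretical maximum accessible surface areas (A^2) per residue
# (Tien et al. 2013), used to normalize raw ASA into relative ASA.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Side-chain SMILES fragments attached at C-alpha; a residue unit is
# "N[C@@H](<frag>)C(=O)" (glycine and proline are special-cased).
# Stereo tags verified by canonicalizing against reference isomeric SMILES
# of the free L-amino acids.
SIDECHAIN_SMILES <- c(
  A = "C",              R = "CCCN=C(N)N",     N = "CC(=O)N",
  D = "CC(=O)O",        C = "CS",             E = "CCC(=O)O",
  Q = "CCC(=O)N",       H = "CC1=CN=CN1",     I = "[C@@H](C)CC",
  L = "CC(C)C",         K = "CCCCN",          M = "CCSC",
  F = "CC1=CC=CC=C1",   S = "CO",             T = "[C@H](O)C",
  W = "CC1=CNC2=CC=CC=C12", Y = "CC1=CC=C(O)C=C1", V = "C(C)C")

#' Monomer table
#'
#' Returns the registered monomer table: the 20 canonical L-amino acids plus
#' their D-counterparts (codes `dA` ... `dY`).  Each entry carries the
#' three-letter name, the average molecular mass of the free amino acid,
#' the side-chain pKa and charge sign when protonated (ionizable residues
#' only), the Eisenberg consensus hydrophobicity value, and the category
#' flags used by the empirical rules.
#'
#' @return A data frame with one row per registered monomer code.
#' @examples
#' mt <- monomer_table()
#' mt[mt$code == "K", ]
#' @export
monomer_table <- function() {
  l <- data.frame(
    code = AA1,
    name3 = unname(AA3[AA1]),
    is_d = FALSE,
    mass = unname(AA_MASS[AA1]),
    pka = unname(AA_PKA[AA1]),
    charge_sign = unname(AA_PKA_SIGN[AA1]),
    eisenberg = unname(EISENBERG[AA1]),
    charged = AA1 %in% CHARGED_SET,
    hydrophobic = AA1 %in% HYDROPHOBIC_SET,
    aromatic = AA1 %in% AROMATIC_SET,
    stringsAsFactors = FALSE
  )
  d <- l
  d$code <- paste0("d", l$code)
  d$name3 <- paste0("D", substr(l$name3, 1, 2))
  d$is_d <- TRUE
  rbind(l, d)
}

# fast lookup: strip the D prefix to reach the parent L constants
base_code <- function(codes) sub("^d", "", codes)
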