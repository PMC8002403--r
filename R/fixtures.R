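# Synthetic protein-peptide complex fixtures.
#
# All structure tests run on these generated PDB files: ideal-geometry
# poly-alanine chains built by internal-coordinate chaining (NeRF) with
# phi/psi set per fixture kind, placed at a controlled interface distance.
# No downloads are required anywhere in the package.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

# NeRF: place atom D bonded to C, with angle B-C-D and dihedral A-B-C-D
place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  bc <- c_ - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(ph),
               bond * sin(th) * sin(ph))
  c_ + cbind(bc, m, n) %*% d_local
}

# ideal poly-alanine backbone (N, CA, C, O, CB per residue)
build_backbone <- function(n_res, phi, psi, omega = 180, cb = TRUE) {
  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  CB <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- as.numeric(place_atom(c(0, 1, 0), N[1, ], CA[1, ],
                                  1.525, 111.2, phi))
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
    if (cb) CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 1.53, 110.4, 122.5)
  }
  res <- lapply(seq_len(n_res), function(i) {
    nm <- c("N", "CA", "C", "O", if (cb) "CB")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], if (cb) CB[i, ])
    data.frame(name = nm, resi = i, xyz1 = xyz[, 1], xyz2 = xyz[, 2],
               xyz3 = xyz[, 3], stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# translate mobile along direction u until the minimum interatomic
# distance to fixed equals gap
translate_to_gap <- function(fixed, mobile, u, gap) {
  u <- u / vnorm(u)
  mindist <- function(t) {
    mo <- sweep(mobile, 2, t * u, "+")
    d2 <- outer(rowSums(fixed^2), rowSums(mo^2), "+") - 2 * fixed %*% t(mo)
    sqrt(max(min(d2), 0))
  }
  lo <- 0; hi <- 200
  while (mindist(hi) < gap) hi <- hi * 2
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (mindist(mid) < gap) lo <- mid else hi <- mid
  }
  sweep(mobile, 2, hi * u, "+")
}

rot180_z_about <- function(xyz, center) {
  rel <- sweep(xyz, 2, center, "-")
  rel[, 1] <- -rel[, 1]
  rel[, 2] <- -rel[, 2]
  sweep(rel, 2, center, "+")
}

#' Generate a synthetic protein-peptide complex fixture
#'
#' Writes a deterministic synthetic PDB complex with a receptor chain "A"
#' and a peptide chain "C", both ideal-geometry poly-alanine:
#' \describe{
#'   \item{helix}{15-residue receptor helix and 12-residue peptide helix
#'     (phi = -57, psi = -47) side by side at a ~4 A interface gap.}
#'   \item{extended}{10-residue receptor strand and 6-residue peptide
#'     strand (phi = -139, psi = 135) at a ~4 A gap.}
#'   \item{hbond_pair}{two short antiparallel strands registered so that
#'     central residues exchange backbone hydrogen bonds across the
#'     interface.}
#'   \item{two_atom}{single CA atom per chain at exactly `gap` Angstrom:
#'     one and only one interface atom pair.}
#'   \item{far_apart}{helix receptor with the peptide displaced 60 A away:
#'     no contacts, no interface hydrogen bonds.}
#' }
#' A tiny seeded coordinate jitter (sd 0.001 A) makes the seed part of the
#' output while preserving every geometric property; the same kind and
#' seed give a byte-identical file.
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed for the coordinate jitter.
#' @param path output PDB path.
#' @param gap interface atom-pair distance for `two_atom`, Angstrom.
#' @return The path, invisibly.
#' @export
make_fixture_complex <- function(kind = c("helix", "extended", "hbond_pair",
                                          "two_atom", "far_apart"),
                                 seed = 1L,
                                 path = tempfile(fileext = ".pdb"),
                                 gap = 3.5) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  if (kind == "two_atom") {
    atoms <- data.frame(
      name = c("CA", "CA"), resi = c(1L, 1L),
      xyz1 = c(0, gap), xyz2 = c(0, 0), xyz3 = c(0, 0),
      chain = c("A", "C"), stringsAsFactors = FALSE)
    atoms$resn <- "GLY"
  } else if (kind == "hbond_pair") {
    rec <- build_backbone(3, phi = -139, psi = 135)
    pep <- build_backbone(3, phi = -139, psi = 135)
    pxyz <- as.matrix(pep[, c("xyz1", "xyz2", "xyz3")])
    rxyz <- as.matrix(rec[, c("xyz1", "xyz2", "xyz3")])
    # antiparallel placement: two-fold rotation about z through the point
    # midway between the strands (tuned for mutual backbone H-bonding)
    center <- c(mean(rxyz[, 1]), mean(rxyz[, 2]) + 2.4, 0)
    pxyz <- rot180_z_about(pxyz, center)
    pep[, c("xyz1", "xyz2", "xyz3")] <- pxyz
    rec$chain <- "A"; pep$chain <- "C"
    atoms <- rbind(rec, pep)
    atoms$resn <- "ALA"
  } else {
    if (kind == "helix" || kind == "far_apart") {
      rec <- build_backbone(15, phi = -57, psi = -47)
      pep <- build_backbone(12, phi = -57, psi = -47)
    } else {
      rec <- build_backbone(10, phi = -139, psi = 135)
      pep <- build_backbone(6, phi = -139, psi = 135)
    }
    rxyz <- as.matrix(rec[, c("xyz1", "xyz2", "xyz3")])
    pxyz <- as.matrix(pep[, c("xyz1", "xyz2", "xyz3")])
    target <- if (kind == "far_apart") 60 else 3.8
    pxyz <- translate_to_gap(rxyz, pxyz, c(0, 1, 0.2), target)
    pep[, c("xyz1", "xyz2", "xyz3")] <- pxyz
    rec$chain <- "A"; pep$chain <- "C"
    atoms <- rbind(rec, pep)
    atoms$resn <- "ALA"
  }
  jit <- matrix(stats::rnorm(3 * nrow(atoms), sd = 0.001), ncol = 3)
  xyz <- as.matrix(atoms[, c("xyz1", "xyz2", "xyz3")]) + jit

  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = atoms$resi, resid = atoms$resn,
                   eleno = seq_len(nrow(atoms)), elety = atoms$name,
                   chain = atoms$chain,
                   elesy = substr(atoms$name, 1, 1))
  invisible(path)
}
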