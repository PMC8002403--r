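# Native implementation of the Kabsch-Sander backbone hydrogen-bond model
# and secondary-structure assignment, plus Shrake-Rupley accessible
# surface area.  Codes use the standard DSSP alphabet
# (H,G,I = helices; E,B = strands/bridges; T = turn; S = bend; '-' = coil).
#
# Hydrogen-bond energy (kcal/mol) between donor NH(i) and acceptor CO(j):
#   E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)
# with the amide hydrogen placed 1 A from N along the direction of the
# previous residue's O->C vector.  A bond is assigned when E is below the
# cutoff (-0.5 kcal/mol by default).

KS_COUPLING <- 0.084 * 332
KS_DEFAULT_CUTOFF <- -0.5

# backbone table from a complex model: one row per residue with N/CA/C/O
# coordinates (NA-padded when an atom is absent)
backbone_table <- function(atoms) {
  keys <- unique(atoms[, c("chain", "resno")])
  keys <- keys[order(keys$chain, keys$resno), ]
  grab <- function(ch, rn, nm) {
    hit <- which(atoms$chain == ch & atoms$resno == rn & atoms$elety == nm)
    if (length(hit)) unlist(atoms[hit[1], c("x", "y", "z")]) else rep(NA_real_, 3)
  }
  res <- lapply(seq_len(nrow(keys)), function(k) {
    ch <- keys$chain[k]; rn <- keys$resno[k]
    resn <- atoms$resn[atoms$chain == ch & atoms$resno == rn][1]
    list(chain = ch, resno = rn, resn = resn,
         N = grab(ch, rn, "N"), CA = grab(ch, rn, "CA"),
         C = grab(ch, rn, "C"), O = grab(ch, rn, "O"))
  })
  res
}

# hydrogen position for each residue's amide (NA for chain starts/proline)
amide_h_positions <- function(bb) {
  n <- length(bb)
  H <- vector("list", n)
  for (i in seq_len(n)) {
    H[[i]] <- rep(NA_real_, 3)
    if (bb[[i]]$resn == "PRO") next
    if (i == 1) next
    prev <- bb[[i - 1]]
    if (prev$chain != bb[[i]]$chain || bb[[i]]$resno - prev$resno != 1L) next
    if (anyNA(prev$C) || anyNA(prev$O) || anyNA(bb[[i]]$N)) next
    v <- prev$C - prev$O
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6) next
    H[[i]] <- bb[[i]]$N + v / nv
  }
  H
}

#' Backbone hydrogen bonds (Kabsch-Sander)
#'
#' Computes backbone amide-to-carbonyl hydrogen bonds over all chains of a
#' complex using the Kabsch-Sander electrostatic model.  Returns one row
#' per (donor residue, acceptor residue) pair with energy below `cutoff`.
#'
#' @param m a `complex_model` (see [load_complex()]).
#' @param cutoff hydrogen-bond energy cutoff in kcal/mol (default -0.5,
#'   the model's own convention).
#' @return A data frame: donor chain/resno, acceptor chain/resno, energy.
#' @export
hbonds_kabsch_sander <- function(m, cutoff = KS_DEFAULT_CUTOFF) {
  atoms <- m$atoms
  bb <- backbone_table(atoms)
  H <- amide_h_positions(bb)
  n <- length(bb)
  CA <- t(vapply(bb, function(r) r$CA, numeric(3)))
  out <- list()
  for (i in seq_len(n)) {          # donor NH(i)
    if (anyNA(H[[i]]) || anyNA(bb[[i]]$N)) next
    for (j in seq_len(n)) {        # acceptor CO(j)
      if (i == j) next
      # the donor's own preceding residue is covalently linked, never a bond
      if (bb[[i]]$chain == bb[[j]]$chain &&
          bb[[i]]$resno - bb[[j]]$resno == 1L) next
      if (anyNA(bb[[j]]$C) || anyNA(bb[[j]]$O)) next
      if (anyNA(CA[i, ]) || anyNA(CA[j, ])) next
      if (sum((CA[i, ] - CA[j, ])^2) > 81) next   # 9 A CA-CA screen
      dON <- sqrt(sum((bb[[i]]$N - bb[[j]]$O)^2))
      dCH <- sqrt(sum((H[[i]] - bb[[j]]$C)^2))
      dOH <- sqrt(sum((H[[i]] - bb[[j]]$O)^2))
      dCN <- sqrt(sum((bb[[i]]$N - bb[[j]]$C)^2))
      if (min(dON, dCH, dOH, dCN) < 0.5) { e <- -9.9 } else {
        e <- KS_COUPLING * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
        e <- max(e, -9.9)
      }
      if (e < cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          donor_chain = bb[[i]]$chain, donor_resno = bb[[i]]$resno,
          acceptor_chain = bb[[j]]$chain, acceptor_resno = bb[[j]]$resno,
          energy = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      acceptor_chain = character(0), acceptor_resno = integer(0),
                      energy = numeric(0)))
  }
  do.call(rbind, out)
}

# secondary structure from the hydrogen-bond list, per chain
assign_ss <- function(bb, hb) {
  n <- length(bb)
  key <- vapply(bb, function(r) paste(r$chain, r$resno), character(1))
  idx_of <- function(ch, rn) match(paste(ch, rn), key)
  # hbond[i, j]: CO(i) accepts from NH(j)
  hmat <- matrix(FALSE, n, n)
  if (nrow(hb)) {
    di <- idx_of(hb$donor_chain, hb$donor_resno)
    ai <- idx_of(hb$acceptor_chain, hb$acceptor_resno)
    hmat[cbind(ai, di)] <- TRUE
  }
  same_chain <- function(i, j) bb[[i]]$chain == bb[[j]]$chain &&
    bb[[j]]$resno - bb[[i]]$resno == j - i
  turn <- function(i, k) {        # k-turn at i: CO(i) <- NH(i+k)
    j <- i + k
    j <= n && same_chain(i, j) && hmat[i, j]
  }
  ss <- rep("-", n)

  # bends (kappa > 70 deg)
  for (i in 3:max(3, n - 2)) {
    if (n < 5) break
    if (!same_chain(i - 2, i + 2)) next
    u <- bb[[i]]$CA - bb[[i - 2]]$CA
    v <- bb[[i + 2]]$CA - bb[[i]]$CA
    if (anyNA(u) || anyNA(v)) next
    ang <- acos(pmin(1, pmax(-1, sum(u * v) /
                (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) * 180 / pi
    if (ang > 70) ss[i] <- "S"
  }
  # turns
  for (k in c(3L, 4L, 5L)) {
    for (i in seq_len(n)) {
      if (turn(i, k)) {
        for (j in (i + 1):(i + k - 1)) if (j <= n && ss[j] == "-") ss[j] <- "T"
      }
    }
  }
  # bridges / strands
  bridge <- rep(FALSE, n)
  for (i in 2:max(2, n - 1)) {
    if (n < 3) break
    for (k in 2:(n - 1)) {
      if (abs(i - k) < 3) next
      para <- (hmat[k - 1, i] && hmat[i, k + 1]) ||
              (hmat[i - 1, k] && hmat[k, i + 1])
      anti <- (hmat[i, k] && hmat[k, i]) ||
              (hmat[i - 1, k + 1] && hmat[k - 1, i + 1])
      if (para || anti) bridge[i] <- TRUE
    }
  }
  for (i in which(bridge)) {
    ss[i] <- if ((i > 1 && bridge[i - 1]) || (i < n && bridge[i + 1])) "E" else "B"
  }
  # helices (3-10, alpha, pi); alpha has priority
  mark_helix <- function(k, code) {
    for (i in 2:max(2, n)) {
      if (i + k > n + 1) break
      if (turn(i - 1, k) && turn(i, k)) {
        for (j in i:(i + k - 1)) {
          if (j <= n && (code == "H" || ss[j] %in% c("-", "T", "S")))
            ss[j] <<- code
        }
      }
    }
  }
  mark_helix(3L, "G")
  mark_helix(5L, "I")
  mark_helix(4L, "H")
  ss
}

# --- Shrake-Rupley accessible surface area ------------------------------

SR_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
              P = 1.80)
SR_PROBE <- 1.4

sphere_points <- function(n = 256L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' Numeric solvent-accessible surface area per atom: each atom is covered
#' with `n_points` quasi-uniform sphere points at its solvent-extended
#' radius; points falling inside any neighbour's extended sphere are
#' occluded.  Probe radius 1.4 A.
#'
#' @param xyz numeric matrix (atoms x 3), Angstrom.
#' @param element character vector of element symbols.
#' @param n_points sphere points per atom.
#' @return numeric vector of per-atom ASA in A^2.
#' @export
shrake_rupley <- function(xyz, element, n_points = 256L) {
  n <- nrow(xyz)
  rad <- SR_RADII[element]
  rad[is.na(rad)] <- 1.8
  rext <- rad + SR_PROBE
  pts <- sphere_points(n_points)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nbr <- setdiff(which(d2 < (rext[i] + max(rext))^2), i)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(p, 2, xyz[j, ], "-")^2)
      acc <- acc & (dj2 > rext[j]^2)
    }
    asa[i] <- 4 * pi * rext[i]^2 * sum(acc) / n_points
  }
  asa
}
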