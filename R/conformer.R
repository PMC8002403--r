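# Single-conformer prediction by distance geometry.
#
# Pipeline: heavy-atom bounds matrix from the molecular graph (bond
# lengths, 1-3 distances from ideal angles, van der Waals lower bounds
# elsewhere) -> triangle-bounds smoothing -> seeded random distance matrix
# within bounds -> classical metric embedding in 3D -> bound-violation
# refinement -> MMFF94 force-field cleanup via Open Babel (hydrogens added
# for minimization, stripped on output by default).

BOND_LENGTH <- list("C-C-1" = 1.53, "C-C-2" = 1.34, "C-N-1" = 1.45,
                    "C-N-2" = 1.29, "N-C-1" = 1.45, "N-C-2" = 1.29,
                    "C-O-1" = 1.41, "C-O-2" = 1.23, "O-C-1" = 1.41,
                    "O-C-2" = 1.23, "C-S-1" = 1.81, "S-C-1" = 1.81)

ideal_bond_length <- function(e1, e2, order) {
  key <- paste(e1, e2, order, sep = "-")
  v <- BOND_LENGTH[[key]]
  if (is.null(v)) 1.5 else v
}

# distance bounds from the bond graph
dg_bounds <- function(graph) {
  n <- nrow(graph$atoms)
  el <- graph$atoms$element
  L <- matrix(2.4, n, n)   # generic heavy-atom lower bound (clash floor)
  U <- matrix(999, n, n)
  diag(L) <- diag(U) <- 0

  # adjacency with per-bond ideal lengths
  blen <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    d <- ideal_bond_length(el[i], el[j], graph$bonds$order[k])
    blen[i, j] <- blen[j, i] <- d
    L[i, j] <- L[j, i] <- d - 0.02
    U[i, j] <- U[j, i] <- d + 0.02
  }
  # sp2 centers: any double bond
  has_double <- rep(FALSE, n)
  dbl <- graph$bonds[graph$bonds$order == 2L, ]
  has_double[c(dbl$i, dbl$j)] <- TRUE

  # geminal (1-3) distances by the law of cosines at the center atom
  nb <- lapply(seq_len(n), function(i) {
    c(graph$bonds$j[graph$bonds$i == i], graph$bonds$i[graph$bonds$j == i])
  })
  for (c_ in seq_len(n)) {
    ns <- nb[[c_]]
    if (length(ns) < 2) next
    theta <- if (has_double[c_]) 120 else 109.47
    ct <- cos(theta * pi / 180)
    for (a in seq_along(ns)) for (b in seq_along(ns)) {
      if (a >= b) next
      i <- ns[a]; j <- ns[b]
      d <- sqrt(blen[c_, i]^2 + blen[c_, j]^2 -
                2 * blen[c_, i] * blen[c_, j] * ct)
      L[i, j] <- L[j, i] <- max(d - 0.06, 0)
      U[i, j] <- U[j, i] <- min(U[i, j], d + 0.06)
    }
  }
  # triangle-bounds smoothing (upper: shortest path; lower: consistency)
  for (k in seq_len(n)) {
    Uk <- outer(U[, k], U[k, ], "+")
    U <- pmin(U, Uk)
  }
  for (k in seq_len(n)) {
    Lk <- pmax(outer(L[, k], -U[k, ], "+"), outer(-U[, k], L[k, ], "+"))
    L <- pmax(L, Lk)
  }
  L <- pmin(L, U)
  list(L = L, U = U)
}

dg_refine <- function(X, L, U, maxit = 300L) {
  n <- nrow(X)
  fn <- function(x) {
    X <- matrix(x, n, 3)
    D <- as.matrix(stats::dist(X))
    over <- pmax(D - U, 0); under <- pmax(L - D, 0)
    sum(over^2 + under^2) / 2
  }
  gr <- function(x) {
    X <- matrix(x, n, 3)
    D <- as.matrix(stats::dist(X))
    over <- pmax(D - U, 0); under <- pmax(L - D, 0)
    S <- (over - under) / pmax(D, 1e-8)
    diag(S) <- 0
    G <- 2 * (X * rowSums(S) - S %*% X)
    as.vector(G)
  }
  res <- stats::optim(as.vector(X), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  matrix(res$par, n, 3)
}

write_sdf <- function(graph, X, path) {
  n <- nrow(graph$atoms); m <- nrow(graph$bonds)
  lines <- c("peptide", "  peptools distance geometry", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              X[i, 1], X[i, 2], X[i, 3], graph$atoms$element[i]))
  }
  for (k in seq_len(m)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", graph$bonds$i[k],
                              graph$bonds$j[k], graph$bonds$order[k]))
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
}

read_sdf_atoms_bonds <- function(path) {
  lines <- readLines(path)
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  m <- as.integer(substr(counts, 4, 6))
  at <- lines[5:(4 + n)]
  xyz <- t(vapply(at, function(l) {
    c(as.numeric(substr(l, 1, 10)), as.numeric(substr(l, 11, 20)),
      as.numeric(substr(l, 21, 30)))
  }, numeric(3)))
  el <- trimws(substr(at, 32, 34))
  bd <- lines[(5 + n):(4 + n + m)]
  bonds <- data.frame(i = as.integer(substr(bd, 1, 3)),
                      j = as.integer(substr(bd, 4, 6)))
  rownames(xyz) <- NULL
  list(xyz = unname(xyz), element = unname(el), bonds = bonds)
}

require_openbabel <- function() {
  if (!nzchar(Sys.which("obabel"))) {
    err_dependency(paste(
      "Open Babel ('obabel') is required for force-field cleanup;",
      "install it e.g. via 'conda install -c conda-forge openbabel'"))
  }
}

mmff_minimize <- function(in_sdf, out_sdf, steps = 500L) {
  require_openbabel()
  status <- suppressWarnings(system2(
    "obabel", c(in_sdf, "-O", out_sdf, "-h", "--minimize",
                "--ff", "MMFF94", "--steps", steps, "--sd"),
    stdout = FALSE, stderr = FALSE))
  status == 0L && file.exists(out_sdf) && length(readLines(out_sdf)) > 4
}

mmff_energy <- function(sdf) {
  if (!nzchar(Sys.which("obenergy"))) return(NA_real_)
  out <- suppressWarnings(system2("obenergy", c("-ff", "MMFF94", sdf),
                                  stdout = TRUE, stderr = FALSE))
  m <- regmatches(out, regexpr("TOTAL ENERGY =\\s*(-?[0-9.]+)", out))
  if (!length(m)) return(NA_real_)
  as.numeric(sub("TOTAL ENERGY =\\s*", "", m[length(m)]))
}

# majority L-configuration check: signed volume of (CA->N, CA->C, CA->CB)
ca_chirality_sign <- function(graph, X) {
  a <- graph$atoms
  s <- 0
  for (ri in unique(a$resi)) {
    nm <- a$name[a$resi == ri]
    if (!("CB" %in% nm)) next
    idx <- function(w) which(a$resi == ri & a$name == w)
    v1 <- X[idx("N"), ] - X[idx("CA"), ]
    v2 <- X[idx("C"), ] - X[idx("CA"), ]
    v3 <- X[idx("CB"), ] - X[idx("CA"), ]
    s <- s + sign(sum(v3 * c(v1[2] * v2[3] - v1[3] * v2[2],
                             v1[3] * v2[1] - v1[1] * v2[3],
                             v1[1] * v2[2] - v1[2] * v2[1])))
  }
  s
}

#' Generate a 3D peptide conformer
#'
#' Predicts one conformer from sequence by distance geometry: a
#' triangle-smoothed distance bounds matrix is sampled (seeded), embedded
#' in three dimensions by classical metric scaling, refined against the
#' bounds, and cleaned up with the MMFF94 force field (Open Babel;
#' hydrogens added for minimization).  The result is deterministic for a
#' fixed seed.  Embedding is retried with fresh samples up to
#' `retry_budget` times before failing.
#'
#' @param p a `peptide` or character sequence.
#' @param seed integer random seed for the distance-matrix sample.
#' @param keep_hydrogens keep minimization hydrogens in the result
#'   (default `FALSE`: heavy atoms only, X-ray-like output).
#' @param retry_budget embedding attempts before an embedding error.
#' @param steps MMFF94 minimization steps.
#' @return An object of class `conformer`: atom table (PDB name, element,
#'   residue index/name, coordinates in Angstrom), `seed`, `energy`
#'   (MMFF94 kcal/mol), `converged`.
#' @examples
#' \donttest{conf <- generate_conformer("GA", seed = 1)}
#' @export
generate_conformer <- function(p, seed = 1L, keep_hydrogens = FALSE,
                               retry_budget = 10L, steps = 500L) {
  p <- as_peptide(p)
  require_openbabel()
  graph <- build_molecular_graph(p)
  bounds <- dg_bounds(graph)
  n <- nrow(graph$atoms)

  set.seed(as.integer(seed))
  ok <- FALSE
  for (attempt in seq_len(retry_budget)) {
    Dm <- matrix(0, n, n)
    r <- matrix(stats::runif(n * n), n, n)
    Dm <- bounds$L + (bounds$U - bounds$L) * (r + t(r)) / 2
    diag(Dm) <- 0
    X <- tryCatch(stats::cmdscale(Dm, k = 3), error = function(e) NULL)
    if (is.null(X) || ncol(X) < 3) next
    X <- dg_refine(X, bounds$L, bounds$U)
    if (ca_chirality_sign(graph, X) < 0) X[, 1] <- -X[, 1]
    # accept when bonded distances are close to target after refinement
    D <- as.matrix(stats::dist(X))
    bd <- abs(D[cbind(graph$bonds$i, graph$bonds$j)] -
              (bounds$U[cbind(graph$bonds$i, graph$bonds$j)] - 0.02))
    if (max(bd) < 0.3) { ok <- TRUE; break }
  }
  if (!ok) err_embedding(sprintf("embedding failed after %d attempts", retry_budget))

  in_sdf <- tempfile(fileext = ".sdf")
  out_sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(in_sdf, out_sdf)), add = TRUE)
  write_sdf(graph, X, in_sdf)
  converged <- mmff_minimize(in_sdf, out_sdf, steps = steps)
  if (!converged) err_embedding("MMFF94 cleanup failed")
  min_mol <- read_sdf_atoms_bonds(out_sdf)
  if (!identical(min_mol$element[seq_len(n)], graph$atoms$element)) {
    err_embedding("atom order not preserved by force-field cleanup")
  }
  energy <- mmff_energy(out_sdf)

  atoms <- graph$atoms
  atoms$x <- min_mol$xyz[seq_len(n), 1]
  atoms$y <- min_mol$xyz[seq_len(n), 2]
  atoms$z <- min_mol$xyz[seq_len(n), 3]
  if (keep_hydrogens && length(min_mol$element) > n) {
    hidx <- (n + 1L):length(min_mol$element)
    # attach each hydrogen to the residue of its bonded heavy atom
    hres <- vapply(hidx, function(h) {
      b <- min_mol$bonds
      partner <- c(b$j[b$i == h], b$i[b$j == h])
      partner <- partner[partner <= n][1]
      if (is.na(partner)) NA_integer_ else atoms$resi[partner]
    }, integer(1))
    hat <- data.frame(name = "H", element = "H", resi = hres,
                      resn = atoms$resn[match(hres, atoms$resi)],
                      x = min_mol$xyz[hidx, 1], y = min_mol$xyz[hidx, 2],
                      z = min_mol$xyz[hidx, 3], stringsAsFactors = FALSE)
    hat <- hat[!is.na(hat$resi), ]
    atoms <- rbind(atoms, hat)
    atoms <- atoms[order(atoms$resi), ]
  }
  structure(list(atoms = atoms, seed = as.integer(seed), energy = energy,
                 converged = converged, sequence = as.character(p),
                 force_field = "MMFF94"),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %s: %d atoms, %d residues, %s energy %.2f kcal/mol (seed %d)\n",
              x$sequence, nrow(x$atoms), max(x$atoms$resi),
              x$force_field, x$energy, x$seed))
  invisible(x)
}

#' Write a conformer as PDB
#'
#' Writes PDB v3.3 ATOM records, serial numbers from 1, residues numbered
#' and ordered N- to C-terminus, with a TER record after the last residue.
#'
#' @param conf a `conformer` object.
#' @param path output file path.
#' @param chain chain identifier (default `"A"`).
#' @return The path, invisibly.
#' @export
write_pdb <- function(conf, path, chain = "A") {
  stopifnot(inherits(conf, "conformer"))
  a <- conf$atoms
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resi, resid = a$resn,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = rep(chain, nrow(a)),
                     elesy = a$element)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) err_io(sprintf("cannot write PDB to '%s'", path))
  # insert TER after the final residue (bio3d writes ATOM/END only)
  lines <- readLines(path)
  last_atom <- max(grep("^ATOM", lines))
  ter <- sprintf("TER   %5d      %3s %s%4d",
                 nrow(a) + 1L, a$resn[nrow(a)], chain, a$resi[nrow(a)])
  writeLines(append(lines, ter, after = last_atom), path)
  invisible(path)
}
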