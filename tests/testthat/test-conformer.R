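conf_dist <- function(conf, ri, ni, rj, nj) {
  a <- conf$atoms
  p <- unlist(a[a$resi == ri & a$name == ni, c("x", "y", "z")])
  q <- unlist(a[a$resi == rj & a$name == nj, c("x", "y", "z")])
  sqrt(sum((p - q)^2))
}

test_that("conformers keep residue bookkeeping and backbone atoms", {
  conf <- generate_conformer("GA", seed = 1)
  a <- conf$atoms
  expect_equal(sort(unique(a$resi)), c(1L, 2L))
  expect_equal(unique(a$resn[a$resi == 1]), "GLY")
  expect_equal(unique(a$resn[a$resi == 2]), "ALA")
  for (ri in 1:2) {
    expect_true(all(c("N", "CA", "C", "O") %in% a$name[a$resi == ri]))
  }
  expect_true(is.finite(conf$energy))
  expect_true(conf$converged)
})

test_that("fixed seeds reproduce identical coordinates", {
  c1 <- generate_conformer("GAV", seed = 7)
  c2 <- generate_conformer("GAV", seed = 7)
  expect_identical(c1$atoms, c2$atoms)
})

test_that("minimized geometry respects ideal bond-length windows", {
  conf <- generate_conformer("ASDF", seed = 3)
  for (ri in 1:4) {
    expect_gt(conf_dist(conf, ri, "N", ri, "CA"), 1.3)
    expect_lt(conf_dist(conf, ri, "N", ri, "CA"), 1.6)
    expect_gt(conf_dist(conf, ri, "CA", ri, "C"), 1.4)
    expect_lt(conf_dist(conf, ri, "CA", ri, "C"), 1.7)
  }
  for (ri in 1:3) {  # peptide bond C(i)-N(i+1)
    d <- conf_dist(conf, ri, "C", ri + 1, "N")
    expect_gt(d, 1.2); expect_lt(d, 1.5)
  }
  # clash sanity: no two non-bonded heavy atoms closer than 1 A
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  D <- as.matrix(dist(xyz))
  g <- build_molecular_graph("ASDF")
  bonded <- matrix(FALSE, nrow(xyz), nrow(xyz))
  bonded[cbind(g$bonds$i, g$bonds$j)] <- TRUE
  bonded <- bonded | t(bonded)
  expect_gt(min(D[!bonded & upper.tri(D)]), 1.0)
})

test_that("hydrogens are kept on request and assigned to residues", {
  heavy <- generate_conformer("GA", seed = 1)
  withh <- generate_conformer("GA", seed = 1, keep_hydrogens = TRUE)
  expect_gt(nrow(withh$atoms), nrow(heavy$atoms))
  expect_true(all(withh$atoms$resi %in% 1:2))
})

test_that("PDB output round-trips coordinates at format precision", {
  conf <- generate_conformer("GA", seed = 1)
  path <- tempfile(fileext = ".pdb")
  write_pdb(conf, path, chain = "B")
  lines <- readLines(path)
  expect_true(any(grepl("^TER", lines)))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  expect_equal(pdb$atom$chain[1], "B")
  expect_equal(pdb$atom$x, conf$atoms$x, tolerance = 1e-3)
  expect_equal(pdb$atom$resid[pdb$atom$resno == 1][1], "GLY")
  # glycine with hydrogens suppressed: N, CA, C, O (+ OXT on the terminus)
  g <- generate_conformer("G", seed = 2)
  expect_equal(nrow(g$atoms), 5L)
  expect_equal(sort(g$atoms$name), sort(c("N", "CA", "C", "O", "OXT")))
})
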