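test_that("ideal helices are coded H in the core with i,i+4 bonds", {
  f <- make_fixture_complex("helix", seed = 1)
  m <- load_complex(f, "C")
  ann <- annotate_structure(m, chain = "C")
  expect_equal(nrow(ann), 12L)
  expect_gte(sum(ann$ss == "H"), 6)            # helix core
  hb <- hbonds_kabsch_sander(m)
  intra <- hb[hb$donor_chain == "C" & hb$acceptor_chain == "C", ]
  expect_true(all(intra$donor_resno - intra$acceptor_resno == 4))
  expect_gte(nrow(intra), 5)
})

test_that("extended chains carry no helix codes", {
  f <- make_fixture_complex("extended", seed = 1)
  m <- load_complex(f, "C")
  ann <- annotate_structure(m)
  expect_false(any(ann$ss %in% c("H", "G", "I")))
  expect_equal(nrow(ann), 16L)   # 10 receptor + 6 peptide residues
})

test_that("relative ASA is normalized into [0, 1] and termini are exposed", {
  f <- make_fixture_complex("helix", seed = 1)
  ann <- annotate_structure(load_complex(f, "C"))
  expect_true(all(ann$rasa >= 0 & ann$rasa <= 1))
  expect_true(all(is.finite(ann$asa)))
  expect_true(all(ann$ss %in% c("H", "B", "E", "G", "I", "T", "S", "-")))
  # chain ends are more exposed than the buried middle on average
  pep <- ann[ann$chain == "C", ]
  expect_gt(pep$rasa[1], min(pep$rasa))
})

test_that("annotation requires a backbone", {
  f <- make_fixture_complex("two_atom", seed = 1)
  expect_error(annotate_structure(load_complex(f, "C")),
               class = "pep_annotation_error")
})

test_that("interface graphs carry mutually-bonded residues with weight 2", {
  f <- make_fixture_complex("hbond_pair", seed = 1)
  m <- load_complex(f, "C")
  g <- hydrogen_bond_graph(m)
  ed <- igraph::as_data_frame(g, "edges")
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$weight, 2)
  # peptide nodes = all peptide residues; protein nodes only if bonded
  roles <- igraph::V(g)$role
  expect_equal(sum(roles == "peptide"), 3L)
  expect_equal(sum(roles == "protein"), 1L)
})

test_that("distant peptides give an edgeless graph of peptide nodes only", {
  f <- make_fixture_complex("far_apart", seed = 1)
  g <- hydrogen_bond_graph(load_complex(f, "C"))
  expect_equal(igraph::ecount(g), 0L)
  expect_true(all(igraph::V(g)$role == "peptide"))
})

test_that("intra-chain helical bonds appear when requested", {
  f <- make_fixture_complex("helix", seed = 1)
  m <- load_complex(f, "C")
  g0 <- hydrogen_bond_graph(m, include_intra = FALSE)
  g1 <- hydrogen_bond_graph(m, include_intra = TRUE)
  expect_gt(igraph::ecount(g1), igraph::ecount(g0))
})

test_that("graph structure is independent of chain processing order", {
  f <- make_fixture_complex("hbond_pair", seed = 1)
  m <- load_complex(f, "C")
  m_rev <- m
  m_rev$atoms <- m_rev$atoms[rev(seq_len(nrow(m_rev$atoms))), ]
  g1 <- hydrogen_bond_graph(m)
  g2 <- hydrogen_bond_graph(m_rev)
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  e1 <- igraph::as_data_frame(g1, "edges")
  e2 <- igraph::as_data_frame(g2, "edges")
  expect_equal(e1[order(e1$from), ], e2[order(e2$from), ], ignore_attr = TRUE)
})

test_that("rendering is deterministic and width tracks bond counts", {
  f <- make_fixture_complex("helix", seed = 1)
  g <- hydrogen_bond_graph(load_complex(f, "C"), include_intra = TRUE)
  p1 <- render_graph(g, tempfile(fileext = ".png"), layout_seed = 9)
  p2 <- render_graph(g, tempfile(fileext = ".png"), layout_seed = 9)
  expect_equal(attr(p1, "layout"), attr(p2, "layout"))
  w <- igraph::E(g)$weight
  expect_equal(attr(p1, "widths"), 2 * w)   # width proportional to weight
  # empty graph renders without error
  fe <- make_fixture_complex("far_apart", seed = 1)
  ge <- hydrogen_bond_graph(load_complex(fe, "C"))
  expect_no_error(render_graph(ge, tempfile(fileext = ".png")))
  # graph export formats
  gml <- tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  expect_true(file.exists(gml))
})
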