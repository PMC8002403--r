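test_that("fixture complexes load with the declared chain roles", {
  f <- make_fixture_complex("helix", seed = 1)
  m <- load_complex(f, "C")
  expect_setequal(unique(m$atoms$chain), c("A", "C"))
  expect_true(all(m$atoms$role[m$atoms$chain == "C"] == "peptide"))
  expect_true(all(m$atoms$role[m$atoms$chain == "A"] == "protein"))
  expect_error(load_complex(f, "Z"), class = "pep_chain_not_found")
  expect_error(load_complex(tempfile(), "A"), class = "pep_io_error")
})

test_that("fixtures are byte-identical for the same kind and seed", {
  f1 <- make_fixture_complex("helix", seed = 5, path = tempfile(fileext = ".pdb"))
  f2 <- make_fixture_complex("helix", seed = 5, path = tempfile(fileext = ".pdb"))
  expect_identical(readLines(f1), readLines(f2))
  f3 <- make_fixture_complex("helix", seed = 6, path = tempfile(fileext = ".pdb"))
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("only the first model of a multi-model file is used", {
  f <- make_fixture_complex("extended", seed = 1)
  atoms <- grep("^ATOM", readLines(f), value = TRUE)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", atoms, "ENDMDL",
               "MODEL     2", atoms, atoms, "ENDMDL", "END"), f2)
  m1 <- load_complex(f, "C")
  m2 <- load_complex(f2, "C")
  expect_equal(nrow(m2$atoms), nrow(m1$atoms))
})

test_that("alternate locations other than A are dropped", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  GLY C   1       3.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- load_complex(f, "C")
  expect_equal(nrow(m$atoms), 2L)
})

test_that("the two-atom fixture gives exactly one contact at 4 A", {
  f <- make_fixture_complex("two_atom", seed = 1, gap = 3.5)
  m <- load_complex(f, "C")
  expect_equal(sum(count_contacts(m, 4.0)$contacts), 1L)
  expect_equal(sum(count_contacts(m, 3.0)$contacts), 0L)
})

test_that("contact profiles equal the brute-force oracle", {
  for (seed in 1:20) {
    f <- random_cloud_complex(seed)
    m <- load_complex(f, "C")
    for (t in c(3, 4, 5)) {
      prof <- count_contacts(m, t)
      expect_equal(prof$contacts, contact_oracle(m, t),
                   label = sprintf("seed %d t %g", seed, t))
    }
  }
})

test_that("contacts are monotone in the threshold and symmetric", {
  f <- make_fixture_complex("extended", seed = 2)
  m <- load_complex(f, "C")
  totals <- vapply(c(2, 3, 4, 5, 6),
                   function(t) sum(count_contacts(m, t)$contacts), numeric(1))
  expect_true(all(diff(totals) >= 0))
  # symmetry: swap the chain roles and recount
  m_swapped <- m
  m_swapped$atoms$role <- ifelse(m$atoms$role == "peptide", "protein", "peptide")
  m_swapped$peptide_chain <- "A"
  expect_equal(sum(count_contacts(m, 4)$contacts),
               sum(count_contacts(m_swapped, 4)$contacts))
  expect_error(count_contacts(m, -1), class = "pep_domain_error")
})
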