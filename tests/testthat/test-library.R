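test_that("pattern expansion enumerates the Cartesian set", {
  lib <- expand_pattern("XRTEX")
  expect_equal(length(lib), 400L)
  expect_true(all(grepl("^.RTE.$", lib)))
  expect_false(is.unsorted(lib))
  expect_equal(expand_pattern("GRTEG"), "GRTEG")
  expect_equal(length(expand_pattern("XX")), 400L)
  expect_equal(length(expand_pattern("XXX")), 8000L)
  expect_error(expand_pattern("XR1X"), class = "pep_pattern_error")
  expect_error(expand_pattern(""), class = "pep_pattern_error")
  expect_error(expand_pattern("XXXXXX"), class = "pep_pattern_error")  # > 1e7
})

test_that("single-position scans cover every residue at every position", {
  lib <- scan_library("AAA")
  expect_equal(length(lib), 58L)     # 3*20 minus two duplicate bases
  expect_equal(length(scan_library("A")), 20L)
  for (i in 1:3) {
    expect_setequal(unique(substr(lib, i, i)), AA20)
  }
})

test_that("sampling is seeded, reproducible and honours frequencies", {
  s1 <- sample_library(100, length = 5, seed = 42)
  s2 <- sample_library(100, length = 5, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_library(100, length = 5, seed = 43)
  expect_false(identical(s1, s3))
  # point-mass rows give a constant library
  fm <- matrix(0, nrow = 3, ncol = 20, dimnames = list(NULL, AA20))
  fm[, "W"] <- 1
  expect_true(all(sample_library(50, frequencies = fm, seed = 1) == "WWW"))
  # degenerate and unnormalized rows are rejected
  bad <- fm; bad[2, ] <- 0
  expect_error(sample_library(10, frequencies = bad), class = "pep_frequency_error")
  bad2 <- fm; bad2[2, "W"] <- 2
  expect_error(sample_library(10, frequencies = bad2), class = "pep_frequency_error")
})

test_that("pooled frequencies of a uniform sample approach uniformity", {
  lib <- sample_library(10000, length = 5, seed = 17)
  pooled <- table(factor(unlist(strsplit(lib, "")), levels = AA20))
  freq <- as.numeric(pooled) / sum(pooled)
  expect_true(all(abs(freq - 0.05) < 0.01))
})

test_that("frequency matrices recover the design", {
  m <- frequency_matrix(expand_pattern("XRTEX"))
  expect_equal(unname(m[2, "R"]), 1)
  expect_equal(unname(m[3, "T"]), 1)
  expect_equal(unname(m[4, "E"]), 1)
  expect_true(all(abs(m[c(1, 5), ] - 0.05) < 1e-12))
  expect_equal(unname(rowSums(m)), rep(1, 5))
  expect_error(frequency_matrix(c("AAA", "AAAA")), class = "pep_length_mismatch")
})

test_that("expansion size is exactly alphabet^k and sequences validate", {
  for (k in 0:3) {
    pat <- paste0(paste(rep("X", k), collapse = ""), "GR")
    expect_equal(length(expand_pattern(pat)), 20^k)
  }
  dlib <- expand_pattern("X", alphabet = c("A", "dA"))
  expect_equal(length(dlib), 2L)
  expect_no_error(lapply(dlib, parse_sequence))
  helms <- vapply(dlib, to_helm, character(1))
  expect_true(any(grepl("\\[dA\\]", helms)))
})

test_that("libraries write as list, FASTA and HELM", {
  seqs <- expand_pattern("XG", alphabet = c("A", "G", "dA"))
  for (fmt in c("list", "fasta", "helm")) {
    f <- tempfile()
    write_library(seqs, f, fmt)
    lines <- readLines(f)
    expect_equal(length(lines), if (fmt == "fasta") 2 * length(seqs) else length(seqs))
  }
})
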