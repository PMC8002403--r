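sol_flags <- function(s) {
  r <- check_solubility_rules(s)
  stats::setNames(r$failed, r$rule)
}

test_that("solubility rules reproduce a hand-built truth table", {
  # columns: sequence, expected R-S1 (charged > 45%), R-S2 (hydrophobic
  # > 45%), R-S3 (|charge at pH 7| > 1)
  cases <- list(
    list("GSGSGSGSGS",            c(FALSE, FALSE, FALSE)),
    list("KKKKK",                 c(TRUE,  FALSE, TRUE)),
    list("IIIIIIIIII",            c(FALSE, TRUE,  FALSE)),
    # exact 45% boundaries pass (strict inequality)
    list("KKKKKKKKKGGGGGGGGGGG",  c(FALSE, FALSE, TRUE)),
    list("KKKKKKKKKKGGGGGGGGGG",  c(TRUE,  FALSE, TRUE)),
    list("AAAAAAAAAGGGGGGGGGGG",  c(FALSE, FALSE, FALSE)),
    list("AAAAAAAAAAGGGGGGGGGG",  c(FALSE, TRUE,  FALSE)),
    list("KD",                    c(TRUE,  FALSE, FALSE)),
    list("E",                     c(TRUE,  FALSE, TRUE)),
    list("G",                     c(FALSE, FALSE, FALSE)),
    list("KR",                    c(TRUE,  FALSE, TRUE)),
    list("GGGGGGGGGGGGGGGGGGGK",  c(FALSE, FALSE, FALSE))
  )
  for (cs in cases) {
    flags <- sol_flags(cs[[1]])
    expect_equal(unname(flags[c("R-S1", "R-S2", "R-S3")]), cs[[2]],
                 label = cs[[1]])
  }
})

test_that("synthesis rules flag the documented liabilities with evidence", {
  r <- check_synthesis_rules("AAAAG")
  expect_true(r$failed[r$rule == "R-X1"])
  expect_match(r$evidence[r$rule == "R-X1"], "AAAA")
  r2 <- check_synthesis_rules("GAVLK")
  expect_false(any(r2$failed))
  expect_true(check_synthesis_rules("ADGK")$failed[2])   # DG motif
  expect_true(check_synthesis_rules("QAKAE")$failed[3])  # N-terminal Gln
  expect_true(check_synthesis_rules("MKRCE")$failed[5])  # M + C
})

test_that("rule reports agree with direct re-evaluation of each statement", {
  set.seed(61)
  for (k in 1:100) {
    s <- random_sequence(sample(2:25, 1))
    aa <- strsplit(s, "")[[1]]
    sol <- check_solubility_rules(s)
    expect_equal(attr(sol, "n_failed"), sum(sol$failed))
    expect_equal(sol$failed[sol$rule == "R-S1"],
                 mean(aa %in% c("D", "E", "K", "R", "H")) > 0.45)
    expect_equal(sol$failed[sol$rule == "R-S2"],
                 mean(aa %in% c("A", "I", "L", "M", "F", "W", "V", "Y")) > 0.45)
    expect_equal(sol$failed[sol$rule == "R-S3"], abs(hh_oracle(s, 7)) > 1)
    syn <- check_synthesis_rules(s)
    expect_equal(attr(syn, "n_failed"), sum(syn$failed))
    expect_equal(syn$failed[syn$rule == "R-X1"], grepl("([A-Z])\\1{3}", s))
    expect_equal(syn$failed[syn$rule == "R-X2"], grepl("D[GP]", s))
    expect_equal(syn$failed[syn$rule == "R-X3"], aa[1] %in% c("Q", "N"))
    expect_equal(syn$failed[syn$rule == "R-X5"],
                 sum(aa %in% c("M", "C", "W")) >= 2)
  }
})

test_that("rule evaluation is pure and complete", {
  a <- check_solubility_rules("KKDDEEGG")
  b <- check_solubility_rules("KKDDEEGG")
  expect_identical(a, b)
  # every registered rule appears exactly once per report
  expect_equal(anyDuplicated(c(a$rule, check_synthesis_rules("KKDDEEGG")$rule)), 0L)
  # JSON serialization works
  expect_match(as.character(rule_report_json(a)), "R-S1")
})
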