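test_that("construction validates dimensions, positivity and id uniqueness", {
  expect_error(decision_problem(matrix(1:4, 1)), "at least 2 alternatives")
  expect_error(decision_problem(matrix("a", 2, 2)), "numeric")
  m0 <- matrix(c(1, 0, 2, 3), 2, 2,
               dimnames = list(c("A1", "A2"), c("C1", "C2")))
  expect_error(decision_problem(m0), "row 'A2', column 'C1'")
  m0[2, 1] <- -1
  expect_error(decision_problem(m0), "strictly positive")
  md <- matrix(1:4, 2, 2, dimnames = list(c("x", "x"), c("C1", "C2")))
  expect_error(decision_problem(md), "duplicate alternative ids")
  mc <- matrix(1:4, 2, 2, dimnames = list(c("A1", "A2"), c("C1", "C1")))
  expect_error(decision_problem(mc), "duplicate criterion ids")
  expect_error(decision_problem(matrix(1, 3, 2), directions = "upward"))
})

test_that("CSV round trip preserves the case-study scores and flags bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  p0 <- case_problem()
  utils::write.csv(data.frame(alternative = rownames(p0$scores), p0$scores),
                   f, row.names = FALSE)
  p <- read_decision_matrix(f)
  expect_equal(unname(p$scores["A1", ]), c(4, 9, 8, 7, 8, 5))
  expect_identical(p$scores, p0$scores)
  expect_identical(unname(p$directions), rep("benefit", 6))

  writeLines(c("id,C1,C2", "A1,1,2"), f)
  expect_error(read_decision_matrix(f), "at least 2 alternatives")
  writeLines(c("id,C1,C2", "A1,1,2", "A2,oops,4"), f)
  expect_error(read_decision_matrix(f), "row 'A2', column 'C1'")
})

test_that("normalization maps benefit columns by x/max and cost by min/x", {
  nm <- normalize_matrix(case_problem())
  expect_equal(unname(nm$values[, "C1"]),
               c(0.4444, 0.8889, 1.0, 0.7778, 0.3333), tolerance = 1e-4)
  expect_equal(unname(nm$ideal), rep(1, 6))
  expect_true(all(nm$values > 0 & nm$values <= 1))
  expect_true(all(nm$ideal >= nm$anti_ideal))

  const <- decision_problem(cbind(C1 = c(3, 3, 3), C2 = c(1, 2, 3)))
  expect_equal(unname(normalize_matrix(const)$values[, "C1"]), rep(1, 3))

  costp <- decision_problem(cbind(C1 = c(2, 4), C2 = c(1, 1)),
                            directions = c("cost", "benefit"))
  expect_equal(unname(normalize_matrix(costp)$values[, "C1"]), c(1, 0.5))
})

test_that("normalization is scale invariant and idempotent on benefit data", {
  for (seed in 1:5) {
    p <- random_problem(seed)
    r1 <- normalize_matrix(p)$values
    scaled <- p$scores
    scaled[, 2] <- scaled[, 2] * 7.3
    r2 <- normalize_matrix(decision_problem(scaled))$values
    expect_equal(r1, r2)
    # renormalizing already-normalized benefit data changes nothing
    r3 <- normalize_matrix(decision_problem(r1))$values
    expect_equal(r3, r1)
  }
})

test_that("synthetic problems are reproducible, in range, and valid", {
  a <- synthetic_problem(5, 6, seed = 1)
  b <- synthetic_problem(5, 6, seed = 1)
  expect_identical(a$scores, b$scores)
  s <- synthetic_problem(3, 4, seed = 7)
  expect_true(all(s$scores >= 1 & s$scores <= 9))
  expect_true(all(s$scores == round(s$scores)))
  for (seed in 1:20) {
    p <- synthetic_problem(50, 10, seed = seed)
    expect_s3_class(p, "decision_problem")
    expect_true(all(p$scores > 0))
  }
  expect_error(synthetic_problem(1, 4), "at least 2")
  expect_error(synthetic_problem(3, 4, scale = c(0, 9)), "scale")
})
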