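# frozen case-study scores, each computed beforehand with a literal
# single-purpose implementation of the method (oriented as stored)
frozen <- list(
  topsis = c(0.292097, 0.712205, 0.718900, 0.627889, 0.289145),
  vikor_q = c(0.875000, 0.064241, 0.144224, 0.036614, 0.908252),
  edas = c(0.234131, 0.680038, 0.756114, 0.603050, 0.227046),
  waspas = c(0.686458, 0.822869, 0.832267, 0.805819, 0.673038),
  promethee2 = c(-0.129675, 0.083775, 0.167800, 0.000125, -0.122025)
)

test_that("benchmark rankers reproduce their frozen case-study scores", {
  p <- case_problem()
  w <- case_weights()
  expect_equal(unname(topsis(p, w)$scores), frozen$topsis, tolerance = 1e-5)
  expect_equal(unname(vikor(p, w)$details$q), frozen$vikor_q, tolerance = 1e-5)
  expect_equal(unname(edas(p, w)$scores), frozen$edas, tolerance = 1e-5)
  expect_equal(unname(waspas(p, w)$scores), frozen$waspas, tolerance = 1e-5)
  expect_equal(unname(promethee2(p, w)$scores), frozen$promethee2,
               tolerance = 1e-5)
})

test_that("case-study rank orders follow the expected preference structure", {
  rks <- rank_alternatives(case_problem(), case_weights())
  rk <- do.call(rbind, lapply(rks, ranking_ranks))
  # A3 tops TOPSIS, EDAS, WASPAS; A4 tops VIKOR; PROMETHEE-II == MARCOS
  expect_equal(unname(rk["topsis", ]), c(4, 2, 1, 3, 5))
  expect_equal(unname(rk["edas", ]), c(4, 2, 1, 3, 5))
  expect_equal(unname(rk["waspas", ]), c(4, 2, 1, 3, 5))
  expect_equal(unname(rk["vikor", ]), c(4, 2, 3, 1, 5))
  expect_equal(unname(rk["promethee2", ]), unname(rk["marcos", ]))
  # A2 second under every method
  expect_true(all(rk[, "A2"] == 2))
})

test_that("TOPSIS matches an independent literal implementation on random data", {
  for (seed in 1:8) {
    p <- random_problem(seed)
    w <- weight_bundle(p)$fused
    expect_equal(unname(topsis(p, w)$scores),
                 topsis_oracle(p$scores, as.numeric(w)), tolerance = 1e-12)
  }
})

test_that("score ranges and structural identities hold", {
  p <- case_problem(); w <- case_weights()
  expect_true(all(topsis(p, w)$scores >= 0 & topsis(p, w)$scores <= 1))
  q <- vikor(p, w)$details$q
  expect_true(all(q >= 0 & q <= 1))
  a <- edas(p, w)$scores
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(sum(promethee2(p, w)$scores), 0, tolerance = 1e-12)
  # WASPAS at lambda = 1 collapses to the MARCOS weighted-sum column
  m <- marcos(p, w)
  expect_equal(unname(waspas(p, w, lambda_mix = 1)$scores),
               unname(m$table[rownames(p$scores), "Q"]))
})

test_that("a dominating alternative wins and a dominated one loses at the extremes", {
  p <- decision_problem(rbind(best = c(9, 9, 9), worst = c(1, 1, 1),
                              mid = c(5, 5, 5)))
  w <- rep(1 / 3, 3)
  expect_equal(unname(topsis(p, w)$ranks[["best"]]), 1)
  q <- vikor(p, w)$details$q
  expect_equal(unname(q[["best"]]), 0)
  expect_equal(unname(q[["worst"]]), 1)
})

test_that("an alternative sitting exactly at the average solution scores 0.5 in EDAS", {
  p <- decision_problem(rbind(lo = c(2, 2), avg = c(4, 4), hi = c(6, 6)))
  a <- edas(p, c(0.5, 0.5))$scores
  expect_equal(unname(a[["avg"]]), 0.5)
})

test_that("adding a dominated duplicate never displaces the incumbent winner", {
  for (seed in 1:8) {
    p <- random_problem(seed, n = 5, m = 4)
    w <- weight_bundle(p)$fused
    for (fn in list(topsis, edas, waspas)) {
      base <- fn(p, w)
      top <- names(which.min(base$ranks))
      dup <- p$scores[top, ] * 0.5
      x2 <- rbind(p$scores, dominated = pmax(dup, 0.01))
      p2 <- decision_problem(x2)
      again <- fn(p2, w)
      expect_equal(names(which.min(again$ranks)), top)
    }
  }
})
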