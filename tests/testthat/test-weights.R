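test_that("all four schemes reproduce the case study's published weights", {
  p <- case_problem()
  expect_equal(unname(entropy_weights(p)), published_weights$entropy,
               tolerance = 5e-4)
  expect_equal(unname(critic_weights(p)), published_weights$critic,
               tolerance = 5e-4)
  expect_equal(unname(merec_weights(p)), published_weights$merec,
               tolerance = 5e-4)
  expect_equal(unname(cilos_weights(p)), published_weights$cilos,
               tolerance = 5e-4)
})

test_that("entropy weighting follows information content", {
  # C5 and C6 of the case study hold identical value multisets -> equal weight
  w <- entropy_weights(case_problem())
  expect_equal(w[["C5"]], w[["C6"]])
  # a constant column carries no information
  p <- decision_problem(cbind(C1 = c(2, 2, 2), C2 = c(1, 5, 9)))
  w <- entropy_weights(p)
  expect_equal(unname(w), c(0, 1))
  # all-constant matrix has no extractable information
  flat <- decision_problem(matrix(3, 3, 3))
  expect_error(entropy_weights(flat), "no|zero|undefined|information")
})

test_that("CRITIC balances dispersion and conflict and ignores sd convention", {
  p <- decision_problem(cbind(C1 = c(1, 2, 3), C2 = c(3, 2, 1)))
  expect_equal(unname(critic_weights(p)), c(0.5, 0.5))
  for (seed in 1:10) {
    q <- random_problem(seed)
    expect_equal(critic_weights(q, sd_type = "sample"),
                 critic_weights(q, sd_type = "population"))
  }
  flat <- decision_problem(cbind(C1 = c(2, 2), C2 = c(1, 3)))
  expect_error(critic_weights(flat), "vary")
})

test_that("linear MEREC equals the literal removal-effect oracle", {
  for (seed in 1:10) {
    p <- random_problem(seed)
    expect_equal(unname(merec_weights(p)), merec_removal_oracle(p),
                 tolerance = 1e-12)
  }
  ones <- decision_problem(matrix(1, 4, 5))
  expect_equal(unname(merec_weights(ones)), rep(1 / 5, 5))
  # logarithmic variant is a different method but still a weight vector
  for (seed in 1:3) {
    w <- merec_weights(random_problem(seed), variant = "logarithmic")
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
  }
})

test_that("CILOS reciprocal mass behaves on hand-checkable matrices", {
  p <- decision_problem(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(unname(cilos_weights(p)), c(0.5, 0.5))
  q <- decision_problem(matrix(c(1, 1, 2, 4), 2, byrow = TRUE))
  # T = (1.5, 1.25)
  expect_equal(unname(cilos_weights(q)), c(1.5, 1.25) / 2.75)
})

test_that("entropy and linear MEREC are invariant to rescaling a column", {
  for (seed in 1:5) {
    p <- random_problem(seed)
    scaled <- p$scores
    scaled[, 3] <- scaled[, 3] * 11
    q <- decision_problem(scaled)
    expect_equal(unname(entropy_weights(p)), unname(entropy_weights(q)))
    expect_equal(unname(merec_weights(p)), unname(merec_weights(q)))
  }
})

test_that("Bonferroni fusion averages pairwise interactions", {
  # identity on identical inputs
  w <- c(0.5, 0.3, 0.2)
  expect_equal(unname(bonferroni_fuse(list(w, w, w))), w)
  # order symmetry and closed-form pair sum vs explicit double loop
  set.seed(42)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    ws <- lapply(seq_len(k), function(x) {
      v <- runif(4)
      v / sum(v)
    })
    f1 <- bonferroni_fuse(ws)
    f2 <- bonferroni_fuse(rev(ws))
    expect_equal(f1, f2)
    w_mat <- do.call(rbind, ws)
    pair <- colSums(w_mat)^2 - colSums(w_mat^2)
    expect_equal(pair, bonferroni_pairsum_oracle(w_mat), tolerance = 1e-12)
    bm <- sqrt(pair / (k * (k - 1)))
    expect_equal(unname(f1), unname(bm / sum(bm)))
  }
  expect_error(bonferroni_fuse(list(w)), "at least 2")
})

test_that("fused case-study weights land near the published vector with the same order", {
  b <- weight_bundle(case_problem())
  expect_lt(max(abs(b$fused - published_weights$fused)), 0.02)
  expect_identical(order(-b$fused), order(-published_weights$fused))
})

test_that("every weighting scheme returns a normalized non-negative vector", {
  for (seed in 1:10) {
    p <- random_problem(seed)
    for (w in list(entropy_weights(p), critic_weights(p), merec_weights(p),
                   cilos_weights(p), weight_bundle(p)$fused)) {
      expect_equal(sum(w), 1, tolerance = 1e-9)
      expect_true(all(w >= 0))
      expect_identical(names(w), colnames(p$scores))
    }
  }
})

test_that("cumulative weight shares sort descending and accumulate to 1", {
  tab <- weight_pareto(case_weights())
  expect_identical(tab$criterion[1], "C1")
  expect_true(all(diff(tab$weight) <= 0))
  expect_equal(tab$cumulative_share[6], 1)
  expect_gt(tab$cumulative_share[3], 0.60)
})
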