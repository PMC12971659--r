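# Shared fixtures and independent reference implementations used as oracles.
# The oracles deliberately reimplement each computation in the most literal
# way possible (explicit loops, literal removals) so that tests compare two
# independent routes to the same quantity.

case_problem <- function() labor_protection_matrix()
case_weights <- function() labor_protection_weights()

# the case study's published per-method weights (4 d.p.)
published_weights <- list(
  entropy = c(0.5110, 0.0785, 0.0647, 0.0628, 0.1415, 0.1415),
  critic  = c(0.2790, 0.1391, 0.1211, 0.1244, 0.1675, 0.1689),
  merec   = c(0.1442, 0.1814, 0.1721, 0.1767, 0.1628, 0.1628),
  cilos   = c(0.2153, 0.1469, 0.1540, 0.1500, 0.1668, 0.1668),
  fused   = c(0.3004, 0.1335, 0.1247, 0.1252, 0.1579, 0.1583)
)

# published rank-frequency counts of the case study's OAT analysis
published_rank_counts <- matrix(
  c(0, 0, 0, 15, 21,
    2, 34, 0, 0, 0,
    22, 3, 9, 0, 2,
    10, 0, 26, 0, 0,
    2, 0, 1, 21, 12),
  nrow = 5, byrow = TRUE,
  dimnames = list(paste0("A", 1:5), 1:5))

random_problem <- function(seed, n = 6, m = 5) {
  synthetic_problem(n, m, seed = seed)
}

random_permutation <- function(n) sample(n)

# literal removal-effect MEREC oracle: recompute P_i^(−j) by deleting the
# term while keeping the 1/m coefficient
merec_removal_oracle <- function(problem) {
  r <- normalize_matrix(problem)$values
  m <- ncol(r)
  p_full <- rowSums(r) / m
  l <- vapply(seq_len(m), function(j) {
    p_drop <- rowSums(r[, -j, drop = FALSE]) / m
    sum(abs(p_full - p_drop))
  }, numeric(1))
  l / sum(l)
}

# explicit double-loop Bonferroni pair sum over ordered pairs k != l
bonferroni_pairsum_oracle <- function(w_mat) {
  k <- nrow(w_mat)
  out <- numeric(ncol(w_mat))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a != b) out <- out + w_mat[a, ] * w_mat[b, ]
    }
  }
  out
}

# literal concordant/discordant pair counting
kendall_oracle <- function(ra, rb) {
  n <- length(ra)
  nc <- nd <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- (ra[i] - ra[j]) * (rb[i] - rb[j])
      if (p > 0) nc <- nc + 1
      if (p < 0) nd <- nd + 1
    }
  }
  (nc - nd) / (n * (n - 1) / 2)
}

# minimal literal TOPSIS used as the independent route
topsis_oracle <- function(x, w) {
  v <- sweep(x, 2, sqrt(colSums(x^2)), "/") %*% diag(w)
  dp <- sqrt(rowSums(sweep(v, 2, apply(v, 2, max))^2))
  dm <- sqrt(rowSums(sweep(v, 2, apply(v, 2, min))^2))
  as.numeric(dm / (dp + dm))
}
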