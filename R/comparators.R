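#' @title Benchmark MCDM rankers
#' @description Five established methods run with the same weight vector so
#'   their rank orders can be compared with MARCOS. Every ranker returns an
#'   `mcdm_ranking` whose `scores` are oriented higher-is-better (VIKOR's Q is
#'   negated for storage; the raw Q is kept in `details`), so downstream
#'   correlation, sensitivity and consensus code is orientation-uniform.
#' @name comparators
NULL

new_ranking <- function(method, scores, details = NULL) {
  structure(list(method = method, scores = scores,
                 ranks = ranks_from_scores(scores), details = details),
            class = "mcdm_ranking")
}

#' @export
print.mcdm_ranking <- function(x, digits = 4, ...) {
  cat(toupper(x$method), "ranking\n")
  print(data.frame(score = round(x$scores, digits), rank = x$ranks), ...)
  invisible(x)
}

direction_sign <- function(problem) {
  ifelse(problem$directions == "benefit", 1, -1)
}

# ---- internal score cores ---------------------------------------------------
# These accept an arbitrary weight vector (the OAT include policy deliberately
# feeds vectors with a negative focal weight); validation lives in the public
# wrappers.

topsis_scores <- function(problem, w) {
  x <- problem$scores
  v <- sweep(sweep(x, 2L, sqrt(colSums(x^2)), "/"), 2L, w, "*")
  benefit <- problem$directions == "benefit"
  ideal <- ifelse(benefit, apply(v, 2L, max), apply(v, 2L, min))
  nadir <- ifelse(benefit, apply(v, 2L, min), apply(v, 2L, max))
  d_plus <- sqrt(rowSums(sweep(v, 2L, ideal)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2L, nadir)^2))
  d_minus / (d_plus + d_minus)
}

vikor_q <- function(problem, w, v) {
  x <- problem$scores
  benefit <- problem$directions == "benefit"
  best <- ifelse(benefit, apply(x, 2L, max), apply(x, 2L, min))
  worst <- ifelse(benefit, apply(x, 2L, min), apply(x, 2L, max))
  rng <- best - worst
  if (all(rng == 0)) {
    stop("all alternatives are identical on every criterion; VIKOR is undefined",
         call. = FALSE)
  }
  d <- sweep(-sweep(x, 2L, best), 2L, ifelse(rng == 0, 1, rng), "/")
  d[, rng == 0] <- 0
  wd <- sweep(d, 2L, w, "*")
  s <- rowSums(wd)
  r <- apply(wd, 1L, max)
  q_s <- if (max(s) > min(s)) (s - min(s)) / (max(s) - min(s)) else rep(0, length(s))
  q_r <- if (max(r) > min(r)) (r - min(r)) / (max(r) - min(r)) else rep(0, length(r))
  q <- v * q_s + (1 - v) * q_r
  names(q) <- rownames(x)
  list(q = q, s = s, r = r)
}

edas_scores <- function(problem, w) {
  x <- problem$scores
  av <- colMeans(x)
  dev <- sweep(x, 2L, av)
  sgn <- direction_sign(problem)
  pda <- sweep(pmax(sweep(dev, 2L, sgn, "*"), 0), 2L, av, "/")
  nda <- sweep(pmax(sweep(dev, 2L, -sgn, "*"), 0), 2L, av, "/")
  sp <- as.numeric(pda %*% w)
  sn <- as.numeric(nda %*% w)
  nsp <- if (max(sp) > 0) sp / max(sp) else rep(1, length(sp))
  nsn <- if (max(sn) > 0) 1 - sn / max(sn) else rep(1, length(sn))
  as_ <- (nsp + nsn) / 2
  names(as_) <- rownames(x)
  list(appraisal = as_, sp = sp, sn = sn)
}

waspas_scores <- function(problem, w, lambda_mix) {
  r <- normalize_matrix(problem)$values
  wsm <- as.numeric(r %*% w)
  wpm <- apply(sweep(r, 2L, w, "^"), 1L, prod)
  q <- lambda_mix * wsm + (1 - lambda_mix) * wpm
  names(q) <- rownames(r)
  list(q = q, wsm = wsm, wpm = wpm)
}

promethee_phi <- function(problem, w) {
  x <- sweep(problem$scores, 2L, direction_sign(problem), "*")
  n <- nrow(x)
  pi_mat <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b) pi_mat[a, b] <- sum(w[x[a, ] > x[b, ]])
    }
  }
  phi <- (rowSums(pi_mat) - colSums(pi_mat)) / (n - 1)
  names(phi) <- rownames(x)
  phi
}

marcos_utility <- function(problem, w) {
  nm <- normalize_matrix(problem)
  r_ext <- rbind(anti_ideal = nm$anti_ideal, nm$values, ideal = nm$ideal)
  u <- sweep(r_ext, 2L, w, "*")
  q <- rowSums(u)
  k_plus <- q / q[["ideal"]]
  k_minus <- q / q[["anti_ideal"]]
  f_plus <- k_minus / (k_plus + k_minus)
  f_minus <- k_plus / (k_plus + k_minus)
  utility <- (k_plus + k_minus) /
    (1 + (1 - f_plus) / f_plus + (1 - f_minus) / f_minus)
  list(weighted = u, q = q, k_plus = k_plus, k_minus = k_minus,
       utility = utility)
}

# ---- public rankers ---------------------------------------------------------

#' TOPSIS ranking
#'
#' Vector (root-sum-square) column normalization, weighting, Euclidean
#' distances to the ideal and negative-ideal solutions, and the closeness
#' coefficient `CC = D- / (D+ + D-)`, ranked descending. `CC` lies in `[0, 1]`.
#'
#' @inheritParams marcos
#' @return An `mcdm_ranking`; `details$cc` holds the closeness coefficients.
#' @export
topsis <- function(problem, weights) {
  stopifnot(inherits(problem, "decision_problem"))
  check_weights(weights, ncol(problem$scores))
  cc <- topsis_scores(problem, as.numeric(weights))
  new_ranking("topsis", cc, details = list(cc = cc))
}

#' VIKOR ranking
#'
#' Linear normalization of regret `d_ij = (f*_j - x_ij) / (f*_j - f-_j)`
#' (orientation-aware), group utility `S = sum(w d)`, individual regret
#' `R = max(w d)`, and the compromise index
#' `Q = v (S - S*) / (S- - S*) + (1 - v) (R - R*) / (R- - R*)`, ranked
#' ascending (lower Q = better). A criterion whose best and worst coincide
#' contributes zero regret. Stored `scores` are `-Q` so that higher is better
#' like every other ranker; `details$q`, `details$s`, `details$r` keep the raw
#' quantities. No acceptable-advantage screening is applied: the full Q order
#' is reported.
#'
#' @inheritParams marcos
#' @param v Compromise coefficient in `[0, 1]` balancing group utility
#'   against individual regret (default 0.5).
#' @return An `mcdm_ranking`.
#' @export
vikor <- function(problem, weights, v = 0.5) {
  stopifnot(inherits(problem, "decision_problem"), v >= 0, v <= 1)
  check_weights(weights, ncol(problem$scores))
  res <- vikor_q(problem, as.numeric(weights), v)
  new_ranking("vikor", -res$q,
              details = list(q = res$q, s = res$s, r = res$r, v = v))
}

#' EDAS ranking
#'
#' Distance-from-average method: with column means `AV_j`, positive and
#' negative distances `PDA = max(0, x - AV)/AV` and `NDA = max(0, AV - x)/AV`
#' (mirrored for cost criteria) are weight-summed to `SP` and `SN`, normalized
#' by their maxima (`NSP = SP/max SP`, `NSN = 1 - SN/max SN`; a zero maximum
#' makes that component 1 for all), and averaged into the appraisal score
#' `AS = (NSP + NSN)/2`, ranked descending.
#'
#' @inheritParams marcos
#' @return An `mcdm_ranking`; `details$appraisal` holds AS.
#' @export
edas <- function(problem, weights) {
  stopifnot(inherits(problem, "decision_problem"))
  check_weights(weights, ncol(problem$scores))
  res <- edas_scores(problem, as.numeric(weights))
  new_ranking("edas", res$appraisal, details = res)
}

#' WASPAS ranking
#'
#' Convex mix of the weighted-sum and weighted-product models on the
#' max-normalized matrix (see [normalize_matrix()]):
#' `Q = lambda * sum(w r) + (1 - lambda) * prod(r^w)`, ranked descending.
#' Strict positivity of the scores guarantees the product term is defined.
#'
#' @inheritParams marcos
#' @param lambda_mix Mixing coefficient in `[0, 1]`; 1 reduces to the pure
#'   weighted sum, 0 to the pure weighted product (default 0.5).
#' @return An `mcdm_ranking`.
#' @export
waspas <- function(problem, weights, lambda_mix = 0.5) {
  stopifnot(inherits(problem, "decision_problem"),
            lambda_mix >= 0, lambda_mix <= 1)
  check_weights(weights, ncol(problem$scores))
  res <- waspas_scores(problem, as.numeric(weights), lambda_mix)
  new_ranking("waspas", res$q,
              details = list(wsm = res$wsm, wpm = res$wpm,
                             lambda_mix = lambda_mix))
}

#' PROMETHEE-II ranking
#'
#' Outranking by net flows with the usual (0/1) preference function on the raw
#' scores: `P_j(a, b) = 1` when `a` strictly beats `b` on criterion `j`
#' (orientation-aware), the weighted pairwise preference is
#' `pi(a, b) = sum_j w_j P_j(a, b)`, and the net flow
#' `phi(a) = (1/(n-1)) sum_{b != a} (pi(a, b) - pi(b, a))`, ranked descending.
#' Net flows always sum to zero.
#'
#' @inheritParams marcos
#' @return An `mcdm_ranking`; `details$phi` holds the net flows.
#' @export
promethee2 <- function(problem, weights) {
  stopifnot(inherits(problem, "decision_problem"))
  check_weights(weights, ncol(problem$scores))
  phi <- promethee_phi(problem, as.numeric(weights))
  new_ranking("promethee2", phi, details = list(phi = phi))
}

#' Run a set of rankers with shared weights
#'
#' @inheritParams marcos
#' @param methods Character vector drawn from `"marcos"`, `"topsis"`,
#'   `"vikor"`, `"edas"`, `"waspas"`, `"promethee2"`.
#' @param v VIKOR compromise coefficient.
#' @param lambda_mix WASPAS mixing coefficient.
#' @return Named list of `mcdm_ranking` objects, in the order requested.
#' @examples
#' rank_alternatives(labor_protection_matrix(), labor_protection_weights())
#' @export
rank_alternatives <- function(problem, weights,
                              methods = c("marcos", "topsis", "vikor",
                                          "edas", "waspas", "promethee2"),
                              v = 0.5, lambda_mix = 0.5) {
  methods <- match.arg(methods, several.ok = TRUE)
  runners <- list(
    marcos = function() marcos(problem, weights),
    topsis = function() topsis(problem, weights),
    vikor = function() vikor(problem, weights, v = v),
    edas = function() edas(problem, weights),
    waspas = function() waspas(problem, weights, lambda_mix = lambda_mix),
    promethee2 = function() promethee2(problem, weights)
  )
  stats::setNames(lapply(methods, function(m) runners[[m]]()), methods)
}

#' Extract the 1-based rank vector from a ranking
#'
#' @param ranking An `mcdm_ranking` (including [marcos()] results).
#' @return Named numeric vector of ranks, 1 = best; ties share the average.
#' @export
ranking_ranks <- function(ranking) {
  stopifnot(inherits(ranking, "mcdm_ranking"))
  ranking$ranks
}
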