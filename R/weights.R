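#' @title Objective criterion weighting
#' @description Four data-driven weighting schemes and a Bonferroni fusion.
#'   Each scheme extracts criterion importance from the structure of the score
#'   matrix itself (dispersion, conflict, removal effect, reciprocal mass)
#'   rather than from stated preferences, and returns a non-negative vector
#'   summing to 1.
#' @name weighting
NULL

new_weight_vector <- function(w, method) {
  if (any(w < -1e-12)) {
    stop(method, " produced a negative weight", call. = FALSE)
  }
  w <- pmax(w, 0)
  w / sum(w)
}

check_weights <- function(weights, m) {
  if (length(weights) != m) {
    stop("weight vector has length ", length(weights), ", expected ", m,
         call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(weights)
}

#' Entropy weights
#'
#' Shannon-entropy weighting on the raw score matrix: column proportions
#' `q_ij = x_ij / sum_i(x_ij)`, entropy `E_j = -sum(q log q) / log(n)` (with
#' the convention `0 log 0 = 0`), and weights proportional to the information
#' content `1 - E_j`. Criteria whose scores are nearly uniform across
#' alternatives carry little weight; a constant column carries none.
#'
#' @param problem A [decision_problem].
#' @return Named numeric weight vector summing to 1.
#' @export
entropy_weights <- function(problem) {
  stopifnot(inherits(problem, "decision_problem"))
  x <- problem$scores
  q <- sweep(x, 2L, colSums(x), "/")
  ql <- q * log(q)
  ql[q == 0] <- 0
  e <- -colSums(ql) / log(nrow(x))
  d <- 1 - e
  if (sum(d) <= 1e-12) {
    stop("all criteria carry zero entropy information (constant columns); ",
         "entropy weights are undefined", call. = FALSE)
  }
  new_weight_vector(d, "entropy")
}

#' CRITIC weights
#'
#' Weights each criterion by its information content
#' `I_j = s_j * sum_k (1 - cor(j, k))`: the product of its dispersion (the
#' standard deviation of the raw column) and its conflict with the other
#' criteria (one minus the Pearson correlation, summed over all criteria;
#' the j = k term contributes zero). The sd convention (sample vs population)
#' rescales every `I_j` by the same factor and cancels in the normalization.
#'
#' @inheritParams entropy_weights
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Named numeric weight vector summing to 1.
#' @export
critic_weights <- function(problem, sd_type = c("sample", "population")) {
  stopifnot(inherits(problem, "decision_problem"))
  sd_type <- match.arg(sd_type)
  x <- problem$scores
  if (any(apply(x, 2L, stats::sd) == 0)) {
    stop("CRITIC requires every criterion column to vary across alternatives",
         call. = FALSE)
  }
  s <- apply(x, 2L, stats::sd)
  if (sd_type == "population") {
    s <- s * sqrt((nrow(x) - 1) / nrow(x))
  }
  gamma <- stats::cor(x)
  info <- s * colSums(1 - gamma)
  new_weight_vector(info, "critic")
}

#' MEREC-style removal-effect weights
#'
#' Measures each criterion's importance by the aggregate shift in alternative
#' scores when the criterion is removed.
#'
#' The default `"linear"` variant scores each alternative as the equal-
#' coefficient mean of its normalized row, `P_i = (1/m) sum_j r_ij` (with
#' `r` from [normalize_matrix()]); removing criterion `j` drops its term while
#' keeping the `1/m` coefficient, so the removal effect reduces in closed form
#' to `L_j = sum_i r_ij / m` and the weights are proportional to the column
#' sums of the normalized matrix.
#'
#' The `"logarithmic"` variant is the canonical MEREC formulation:
#' inverse (cost-style) normalization, `S_i = ln(1 + mean_j |ln r'_ij|)`,
#' literal removal of each criterion, and weights proportional to
#' `E_j = sum_i |S_ij' - S_i|`. It is provided for comparison; the two
#' variants generally differ.
#'
#' @inheritParams entropy_weights
#' @param variant `"linear"` (default) or `"logarithmic"`.
#' @return Named numeric weight vector summing to 1.
#' @export
merec_weights <- function(problem, variant = c("linear", "logarithmic")) {
  stopifnot(inherits(problem, "decision_problem"))
  variant <- match.arg(variant)
  m <- ncol(problem$scores)
  if (variant == "linear") {
    r <- normalize_matrix(problem)$values
    l <- colSums(r) / m
    return(new_weight_vector(l, "merec"))
  }
  # canonical logarithmic form on inverse-normalized scores
  x <- problem$scores
  rp <- x
  for (j in seq_len(m)) {
    rp[, j] <- if (problem$directions[j] == "benefit") {
      min(x[, j]) / x[, j]
    } else {
      x[, j] / max(x[, j])
    }
  }
  al <- abs(log(rp))
  s_full <- log(1 + rowMeans(al))
  e <- vapply(seq_len(m), function(j) {
    s_drop <- log(1 + rowMeans(al[, -j, drop = FALSE]))
    sum(abs(s_drop - s_full))
  }, numeric(1L))
  names(e) <- colnames(x)
  new_weight_vector(e, "merec")
}

#' CILOS-style reciprocal-mass weights
#'
#' Weights proportional to the cumulative reciprocal of the raw scores,
#' `T_j = sum_i 1 / x_ij`, normalized across criteria. Criteria on which
#' alternatives score low (large reciprocal mass, i.e. a wide gap to ideal
#' performance) receive more weight. This reciprocal-sum formulation is a
#' deliberate simplification of the classical CILOS impact-loss matrix and is
#' only defined for strictly positive scores.
#'
#' @inheritParams entropy_weights
#' @return Named numeric weight vector summing to 1.
#' @export
cilos_weights <- function(problem) {
  stopifnot(inherits(problem, "decision_problem"))
  t_j <- colSums(1 / problem$scores)
  new_weight_vector(t_j, "cilos")
}

#' Fuse weight vectors with a Bonferroni mean
#'
#' Aggregates K weight vectors criterion-wise with the Bonferroni mean of
#' orders p = q = 1,
#' `BM_j = sqrt( (1/(K(K-1))) * sum_{k != l} w_j^(k) w_j^(l) )`,
#' then normalizes to sum 1. Averaging over pairwise products lets agreement
#' between schemes reinforce a criterion while a single outlying scheme is
#' damped; fusing K identical vectors returns that vector unchanged.
#'
#' @param weights_list List of K >= 2 numeric weight vectors of equal length
#'   (each summing to 1), e.g. the result of [weight_bundle()] methods.
#' @return Named numeric weight vector summing to 1.
#' @export
bonferroni_fuse <- function(weights_list) {
  if (!is.list(weights_list) || length(weights_list) < 2L) {
    stop("need at least 2 weight vectors to fuse", call. = FALSE)
  }
  k <- length(weights_list)
  m <- length(weights_list[[1L]])
  w <- do.call(rbind, lapply(weights_list, function(v) {
    check_weights(v, m)
    as.numeric(v)
  }))
  colnames(w) <- names(weights_list[[1L]])
  # sum over ordered pairs k != l equals (colsum)^2 - colsum of squares
  pair_sum <- colSums(w)^2 - colSums(w^2)
  bm <- sqrt(pair_sum / (k * (k - 1)))
  new_weight_vector(bm, "bonferroni")
}

#' Compute all objective weighting schemes and their fusion
#'
#' Convenience wrapper running [entropy_weights()], [critic_weights()],
#' [merec_weights()] and [cilos_weights()] on one problem and fusing them with
#' [bonferroni_fuse()].
#'
#' @inheritParams entropy_weights
#' @return An object of class `weight_bundle`: list with elements `entropy`,
#'   `critic`, `merec`, `cilos` and `fused`, each a weight vector summing to 1.
#' @examples
#' weight_bundle(labor_protection_matrix())
#' @export
weight_bundle <- function(problem) {
  methods <- list(entropy = entropy_weights(problem),
                  critic = critic_weights(problem),
                  merec = merec_weights(problem),
                  cilos = cilos_weights(problem))
  structure(c(methods, list(fused = bonferroni_fuse(methods))),
            class = "weight_bundle")
}

#' @export
print.weight_bundle <- function(x, digits = 4, ...) {
  cat("Objective criterion weights\n")
  tab <- do.call(rbind, lapply(x, as.numeric))
  colnames(tab) <- names(x$fused)
  print(round(tab, digits), ...)
  invisible(x)
}

#' Cumulative weight shares
#'
#' Sorts a weight vector in descending order and reports each criterion's
#' share together with the running cumulative share — the table behind a
#' Pareto chart of criterion dominance.
#'
#' @param weights Named numeric weight vector summing to 1.
#' @return Data frame with columns `criterion`, `weight`, `cumulative_share`.
#' @export
weight_pareto <- function(weights) {
  check_weights(weights, length(weights))
  if (is.null(names(weights))) {
    names(weights) <- paste0("C", seq_along(weights))
  }
  ord <- order(-as.numeric(weights))
  w <- as.numeric(weights)[ord]
  data.frame(criterion = names(weights)[ord],
             weight = w,
             cumulative_share = cumsum(w),
             row.names = NULL)
}
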