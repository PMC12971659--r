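#' One-at-a-time weight perturbation scenarios
#'
#' For each focal criterion `h`, perturbation level `eps` and sign, the focal
#' weight is shifted by the signed `eps` and the mass is redistributed evenly
#' over the other `m - 1` criteria:
#' `w'_h = w_h + eps`, `w'_j = w_j - eps / (m - 1)` for `j != h`.
#' Every perturbed vector therefore still sums to 1, but a large negative
#' perturbation can push the focal weight below zero; such scenarios are
#' flagged infeasible rather than silently repaired. Scenarios are ordered
#' criterion-major, then by level, then sign (+ before -), giving stable
#' scenario ids.
#'
#' @param base_weights Numeric weight vector (non-negative, sums to 1).
#' @param eps_levels Positive perturbation magnitudes
#'   (default `c(0.05, 0.10, 0.15)`). Both signs are always generated.
#' @return An object of class `scenario_set`: list with `weights` (scenario x
#'   criterion matrix of perturbed vectors) and `info` (data frame with
#'   `criterion`, `eps` (signed), `feasible`).
#' @examples
#' oat_scenarios(labor_protection_weights())
#' @export
oat_scenarios <- function(base_weights, eps_levels = c(0.05, 0.10, 0.15)) {
  m <- length(base_weights)
  check_weights(base_weights, m)
  if (any(eps_levels < 0)) stop("eps levels must be non-negative", call. = FALSE)
  crits <- names(base_weights)
  if (is.null(crits)) crits <- paste0("C", seq_len(m))
  rows <- list()
  info <- list()
  for (h in seq_len(m)) {
    for (e in eps_levels) {
      for (sgn in c(1, -1)) {
        w2 <- as.numeric(base_weights)
        w2[h] <- w2[h] + sgn * e
        w2[-h] <- w2[-h] - sgn * e / (m - 1)
        rows[[length(rows) + 1L]] <- w2
        info[[length(info) + 1L]] <- data.frame(
          criterion = crits[h], eps = sgn * e, feasible = all(w2 >= 0))
      }
    }
  }
  w_mat <- do.call(rbind, rows)
  colnames(w_mat) <- crits
  info <- do.call(rbind, info)
  rownames(w_mat) <- rownames(info) <-
    sprintf("%s%+g", info$criterion, info$eps)
  structure(list(weights = w_mat, info = info, base = base_weights),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("OAT scenario set: ", nrow(x$weights), " scenarios (",
      sum(!x$info$feasible), " infeasible)\n", sep = "")
  print(x$info, ...)
  invisible(x)
}

#' Re-rank alternatives under perturbed weights
#'
#' Runs the chosen ranker once per scenario and tabulates how often each
#' alternative lands on each rank. Infeasible scenarios (negative focal
#' weight) are handled by `policy`:
#' \describe{
#'   \item{include}{use the perturbed vector as-is, negative weight and all
#'     (default: keeps the scenario universe complete at `m * levels * 2`)}
#'   \item{skip}{drop infeasible scenarios from the tabulation}
#'   \item{clamp}{floor negative weights at zero and renormalize to sum 1}
#' }
#'
#' @param problem A [decision_problem].
#' @param scenarios A [oat_scenarios()] result.
#' @param ranker One of the method ids accepted by [rank_alternatives()]
#'   (default `"marcos"`).
#' @param policy `"include"`, `"skip"` or `"clamp"`.
#' @return An object of class `rank_frequency`: list with `counts`
#'   (alternatives x ranks matrix; each row sums to the number of tabulated
#'   scenarios), `denominator`, `policy` and `ranker`.
#' @export
run_sensitivity <- function(problem, scenarios, ranker = "marcos",
                            policy = c("include", "skip", "clamp")) {
  stopifnot(inherits(problem, "decision_problem"),
            inherits(scenarios, "scenario_set"))
  policy <- match.arg(policy)
  if (ncol(scenarios$weights) != ncol(problem$scores)) {
    stop("scenario weights do not match the problem's criteria", call. = FALSE)
  }
  n <- nrow(problem$scores)
  counts <- matrix(0L, n, n,
                   dimnames = list(rownames(problem$scores), seq_len(n)))
  kept <- 0L
  for (s in seq_len(nrow(scenarios$weights))) {
    w <- scenarios$weights[s, ]
    if (any(w < 0)) {
      if (policy == "skip") next
      if (policy == "clamp") {
        w <- pmax(w, 0)
        w <- w / sum(w)
      }
    }
    rks <- scenario_ranks(problem, w, ranker)
    kept <- kept + 1L
    for (i in seq_len(n)) {
      counts[i, ceiling(rks[i])] <- counts[i, ceiling(rks[i])] + 1L
    }
  }
  structure(list(counts = counts, denominator = kept,
                 policy = policy, ranker = ranker),
            class = "rank_frequency")
}

# one scenario re-ranking; calls the internal score cores directly because
# perturbed vectors may carry a (deliberate) negative focal weight under the
# include policy, which the public wrappers reject
scenario_ranks <- function(problem, w, ranker, v = 0.5, lambda_mix = 0.5) {
  alt <- rownames(problem$scores)
  scores <- switch(
    ranker,
    marcos = marcos_utility(problem, w)$utility[alt],
    topsis = topsis_scores(problem, w),
    vikor = -vikor_q(problem, w, v)$q,
    edas = edas_scores(problem, w)$appraisal,
    waspas = waspas_scores(problem, w, lambda_mix)$q,
    promethee2 = promethee_phi(problem, w),
    stop("unknown ranker id: ", ranker, call. = FALSE)
  )
  names(scores) <- alt
  ranks_from_scores(scores)
}

#' @export
print.rank_frequency <- function(x, ...) {
  cat("Rank frequencies over ", x$denominator, " scenarios (",
      x$ranker, ", policy = ", x$policy, ")\n", sep = "")
  print(x$counts, ...)
  invisible(x)
}

#' Stability Index
#'
#' Fraction of evaluation scenarios in which an alternative appears within the
#' top-k ranks. The scenario universe can be a [run_sensitivity()] frequency
#' table (OAT scenarios), a list of method rankings (methods as scenarios), or
#' a bare counts matrix with ranks as columns.
#'
#' @param x A `rank_frequency`, a list of `mcdm_ranking` objects, or an
#'   alternatives x ranks count matrix.
#' @param k Top-k cutoff, `1 <= k <= n`.
#' @param denominator Scenario count for a bare matrix (defaults to its row
#'   sums, which must then be equal).
#' @return Named numeric vector of SI values in `[0, 1]`, one per alternative.
#' @examples
#' rks <- rank_alternatives(labor_protection_matrix(), labor_protection_weights())
#' stability_index(rks, k = 1)
#' @export
stability_index <- function(x, k, denominator = NULL) {
  if (inherits(x, "rank_frequency")) {
    return(stability_index(x$counts, k, x$denominator))
  }
  if (is.list(x) && !is.matrix(x)) {
    rk <- extract_rank_matrix(x)
    n <- ncol(rk)
    counts <- matrix(0L, n, n, dimnames = list(colnames(rk), seq_len(n)))
    for (s in seq_len(nrow(rk))) {
      for (i in seq_len(n)) {
        counts[i, ceiling(rk[s, i])] <- counts[i, ceiling(rk[s, i])] + 1L
      }
    }
    return(stability_index(counts, k, nrow(rk)))
  }
  counts <- as.matrix(x)
  n_ranks <- ncol(counts)
  if (k < 1 || k > n_ranks) {
    stop("`k` must be between 1 and ", n_ranks, call. = FALSE)
  }
  if (is.null(denominator)) {
    denominator <- unique(rowSums(counts))
    if (length(denominator) != 1L) {
      stop("rows tabulate different scenario counts; pass `denominator`",
           call. = FALSE)
    }
  }
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  rowSums(counts[, seq_len(k), drop = FALSE]) / denominator
}
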