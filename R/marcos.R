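#' MARCOS ranking
#'
#' Measurement of Alternatives and Ranking according to Compromise Solution.
#' The normalized matrix is weighted (`u_ij = r_ij * w_j`), ideal and
#' anti-ideal reference rows (the columnwise maxima and minima of `r`) are
#' appended, and each row is summed to an overall score `Q`. Two benchmark
#' ratios follow: `k_plus = Q / Q_ideal` and `k_minus = Q / Q_anti`. The final
#' utility blends them through
#' \deqn{U = (k^+ + k^-) / (1 + (1 - f^+)/f^+ + (1 - f^-)/f^-)}
#' with `f+ = k^- / (k^+ + k^-)` and `f^- = k^+ / (k^+ + k^-)`; alternatives
#' are ranked by descending `U`. `U` is strictly increasing in `Q` at fixed
#' references, so MARCOS never reverses the weighted-sum order within one run
#' — the utility rescales it between the anti-ideal and ideal anchors.
#'
#' With all-benefit criteria and weights summing to 1 the ideal row normalizes
#' to all ones, so `Q_ideal = 1` and `k_plus` equals `Q` itself.
#'
#' @param problem A [decision_problem].
#' @param weights Numeric weight vector over the problem's criteria,
#'   non-negative and summing to 1.
#' @return An object of class `marcos`: list with `weighted` (the weighted
#'   normalized matrix including `anti_ideal` and `ideal` rows), `table` (data
#'   frame of Q, k_plus, k_minus, utility for every row including the
#'   references), `scores` (utilities of the alternatives only), and `ranks`
#'   (1-based, 1 = best).
#' @examples
#' marcos(labor_protection_matrix(), labor_protection_weights())
#' @export
marcos <- function(problem, weights) {
  stopifnot(inherits(problem, "decision_problem"))
  check_weights(weights, ncol(problem$scores))
  core <- marcos_utility(problem, as.numeric(weights))
  alt <- rownames(problem$scores)
  structure(list(
    method = "marcos",
    weighted = core$weighted,
    table = data.frame(Q = core$q, k_plus = core$k_plus,
                       k_minus = core$k_minus, utility = core$utility,
                       row.names = names(core$q)),
    scores = core$utility[alt],
    ranks = ranks_from_scores(core$utility[alt])
  ), class = c("marcos", "mcdm_ranking"))
}

#' @export
print.marcos <- function(x, digits = 4, ...) {
  cat("MARCOS ranking\n")
  tab <- round(x$table, digits)
  tab$rank <- NA
  tab[names(x$ranks), "rank"] <- x$ranks
  print(tab, ...)
  invisible(x)
}
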