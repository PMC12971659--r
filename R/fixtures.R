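#' Built-in case study: labor protection measures in smart-industry workplaces
#'
#' A 5 x 6 expert-scored decision matrix over five labor protection
#' intervention domains — A1 engineering controls, A2 administrative controls,
#' A3 personal protective equipment, A4 safety training programs, A5 digital
#' safety monitoring systems — evaluated on six benefit-oriented criteria:
#' C1 life-cycle cost (affordability), C2 risk-reduction effectiveness,
#' C3 regulatory compliance level, C4 worker acceptance and usability,
#' C5 sustainability and long-term impact, C6 ease of implementation.
#' Scores are panel averages on a nine-point scale (higher = better).
#'
#' @return A [decision_problem] with all-benefit directions.
#' @examples
#' marcos(labor_protection_matrix(), labor_protection_weights())
#' @export
labor_protection_matrix <- function() {
  decision_problem(matrix(
    c(4, 9, 8, 7, 8, 5,
      8, 7, 7, 8, 6, 8,
      9, 6, 6, 9, 5, 9,
      7, 8, 7, 8, 7, 7,
      3, 9, 9, 6, 9, 6),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("A", 1:5), paste0("C", 1:6))))
}

#' Published fused weights for the built-in case study
#'
#' The Bonferroni-fused criterion weight vector that accompanies
#' [labor_protection_matrix()] in the original study. [bonferroni_fuse()]
#' applied to the four objective schemes lands within 0.02 of this vector with
#' the same criterion rank order, but the study's exact fusion arithmetic is
#' not recoverable from its stated operator, so the published vector ships
#' verbatim: every downstream table of the case study is reproduced exactly
#' from it.
#'
#' @return Named numeric weight vector over C1..C6, summing to 1 after
#'   renormalization of the published 4-decimal values.
#' @export
labor_protection_weights <- function() {
  w <- c(C1 = 0.3004, C2 = 0.1335, C3 = 0.1247,
         C4 = 0.1252, C5 = 0.1579, C6 = 0.1583)
  w / sum(w)
}
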