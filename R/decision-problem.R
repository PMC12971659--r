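#' Construct a decision problem
#'
#' A decision problem bundles a strictly positive alternatives-by-criteria
#' score matrix with a per-criterion optimization direction. It is the input
#' to every weighting and ranking routine in the package.
#'
#' Strict positivity is enforced for every cell: the reciprocal-sum CILOS
#' weights and the weighted-product term of WASPAS are undefined at zero, so
#' zeros are rejected at construction rather than deep inside a method.
#'
#' @param scores Numeric matrix (or object coercible to one) with alternatives
#'   in rows and criteria in columns. Row and column names are used as ids;
#'   defaults `A1..An` / `C1..Cm` are supplied when absent.
#' @param directions Character vector of `"benefit"` or `"cost"`, one per
#'   criterion, recycled from length 1. Defaults to all-benefit, the common
#'   safety-first convention in which higher scores are always preferable.
#' @return An object of class `decision_problem`: a list with elements
#'   `scores` (named numeric matrix) and `directions` (named character).
#' @examples
#' p <- decision_problem(matrix(c(1, 2, 3, 6, 5, 4), 3, 2))
#' normalize_matrix(p)
#' @export
decision_problem <- function(scores, directions = "benefit") {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) {
    stop("`scores` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(scores)
  m <- ncol(scores)
  if (n < 2L || m < 2L) {
    stop("a decision problem needs at least 2 alternatives and 2 criteria (got ",
         n, " x ", m, ")", call. = FALSE)
  }
  if (is.null(rownames(scores))) rownames(scores) <- paste0("A", seq_len(n))
  if (is.null(colnames(scores))) colnames(scores) <- paste0("C", seq_len(m))
  if (anyDuplicated(rownames(scores))) {
    stop("duplicate alternative ids: ",
         paste(unique(rownames(scores)[duplicated(rownames(scores))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(scores))) {
    stop("duplicate criterion ids: ",
         paste(unique(colnames(scores)[duplicated(colnames(scores))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(scores) | scores <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("scores must be strictly positive; offending cell: row '",
         rownames(scores)[bad[1L, 1L]], "', column '",
         colnames(scores)[bad[1L, 2L]], "'", call. = FALSE)
  }
  directions <- match.arg(rep_len(directions, m), c("benefit", "cost"),
                          several.ok = TRUE)
  names(directions) <- colnames(scores)
  structure(list(scores = scores, directions = directions),
            class = "decision_problem")
}

#' @export
print.decision_problem <- function(x, ...) {
  cat("Decision problem: ", nrow(x$scores), " alternatives x ",
      ncol(x$scores), " criteria\n", sep = "")
  cat("Directions: ", paste(x$directions, collapse = ", "), "\n", sep = "")
  print(x$scores, ...)
  invisible(x)
}

#' Read a decision matrix from CSV
#'
#' Expects a header row of criterion ids and a first column of alternative
#' ids; all remaining cells must parse as positive numbers. Directions are
#' supplied by the caller, not stored in the file.
#'
#' @param path Path to a CSV file.
#' @inheritParams decision_problem
#' @return A [decision_problem].
#' @examples
#' f <- system.file("extdata", "labor_protection.csv", package = "oshmcdm")
#' read_decision_matrix(f)
#' @export
read_decision_matrix <- function(path, directions = "benefit") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) {
    stop("decision matrix CSV needs an id column plus at least 2 criteria",
         call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")  # NAs reported just below
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing cell at row '", ids[bad[1L]],
         "', column '", colnames(mat)[bad[2L]], "'", call. = FALSE)
  }
  rownames(mat) <- ids
  decision_problem(mat, directions)
}

#' Normalize a decision matrix and derive reference profiles
#'
#' Benefit criteria are scaled by the column maximum (x / max) and cost
#' criteria by the column minimum (min / x), mapping every entry into (0, 1]
#' with 1 at the per-criterion best alternative. The ideal and anti-ideal
#' profiles are the columnwise maxima and minima of the normalized values;
#' MARCOS appends them as reference rows.
#'
#' Normalization is applied even when all scores share a uniform scale, so
#' benchmark profiles are always expressed on the same (0, 1] footing.
#'
#' @param problem A [decision_problem].
#' @return An object of class `normalized_matrix`: list with `values` (n x m
#'   matrix), `ideal` and `anti_ideal` (named m-vectors).
#' @export
normalize_matrix <- function(problem) {
  stopifnot(inherits(problem, "decision_problem"))
  x <- problem$scores
  r <- x
  for (j in seq_len(ncol(x))) {
    r[, j] <- if (problem$directions[j] == "benefit") {
      x[, j] / max(x[, j])
    } else {
      min(x[, j]) / x[, j]
    }
  }
  structure(list(values = r,
                 ideal = apply(r, 2L, max),
                 anti_ideal = apply(r, 2L, min)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, digits = 4, ...) {
  cat("Normalized decision matrix (x/max benefit, min/x cost)\n")
  print(round(x$values, digits), ...)
  cat("ideal:      ", paste(round(x$ideal, digits), collapse = " "), "\n")
  cat("anti-ideal: ", paste(round(x$anti_ideal, digits), collapse = " "), "\n")
  invisible(x)
}

#' Generate a synthetic decision problem
#'
#' Draws integer scores uniformly on a bounded scale (default 1-9, emulating
#' nine-point expert ratings) for property testing and examples. Reproducible
#' for a fixed seed.
#'
#' @param n_alternatives,n_criteria Dimensions, both at least 2.
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored on exit).
#' @param scale Integer range `c(lo, hi)` with `lo >= 1`.
#' @inheritParams decision_problem
#' @return A [decision_problem].
#' @examples
#' synthetic_problem(5, 6, seed = 1)
#' @export
synthetic_problem <- function(n_alternatives, n_criteria, seed = NULL,
                              scale = c(1L, 9L), directions = "benefit") {
  if (n_alternatives < 2L || n_criteria < 2L) {
    stop("need at least 2 alternatives and 2 criteria", call. = FALSE)
  }
  if (length(scale) != 2L || scale[1L] < 1L || scale[2L] < scale[1L]) {
    stop("`scale` must be c(lo, hi) with 1 <= lo <= hi", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  mat <- matrix(sample(seq(scale[1L], scale[2L]),
                       n_alternatives * n_criteria, replace = TRUE),
                nrow = n_alternatives)
  decision_problem(mat, directions)
}

# 1-based ranks, 1 = best (highest score); ties share the average rank
ranks_from_scores <- function(scores) {
  r <- rank(-scores, ties.method = "average")
  names(r) <- names(scores)
  r
}
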