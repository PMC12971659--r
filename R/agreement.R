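#' Kendall's tau (tau-a) between two rank vectors
#'
#' Counts concordant and discordant pairs over all `n(n-1)/2` pairs and
#' returns `(Nc - Nd) / (n(n-1)/2)`. Tied pairs count as neither concordant
#' nor discordant but the denominator is not tie-corrected (tau-a).
#'
#' @param rank_a,rank_b Numeric rank vectors of equal length >= 2 over the
#'   same alternatives (in the same order).
#' @return Correlation in `[-1, 1]`.
#' @examples
#' kendall_tau(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4)) # one adjacent swap: 0.8
#' @export
kendall_tau <- function(rank_a, rank_b) {
  n <- length(rank_a)
  if (length(rank_b) != n) stop("rank vectors differ in length", call. = FALSE)
  if (n < 2L) stop("need at least 2 alternatives", call. = FALSE)
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- s + sign(rank_a[i] - rank_a[j]) * sign(rank_b[i] - rank_b[j])
    }
  }
  s / (n * (n - 1) / 2)
}

#' Spearman's rho between two rank vectors
#'
#' The classical difference formula `1 - 6 sum(d^2) / (n (n^2 - 1))` for
#' tie-free ranks; with ties it falls back to the Pearson moment correlation
#' of the rank vectors (the two coincide when there are no ties).
#'
#' @inheritParams kendall_tau
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(rank_a, rank_b) {
  n <- length(rank_a)
  if (length(rank_b) != n) stop("rank vectors differ in length", call. = FALSE)
  if (n < 2L) stop("need at least 2 alternatives", call. = FALSE)
  if (anyDuplicated(rank_a) || anyDuplicated(rank_b)) {
    return(stats::cor(rank_a, rank_b))
  }
  1 - 6 * sum((rank_a - rank_b)^2) / (n * (n^2 - 1))
}

#' Pairwise rank-correlation matrices across rankings
#'
#' Builds the M x M Kendall tau-a and Spearman rho matrices over a set of
#' rankings of the same alternatives, plus per-method row means.
#'
#' Row means are computed over ALL M entries including the diagonal
#' self-correlation of 1 by default — the convention used when summarizing a
#' method's overall concordance in the shipped case study — and over the M - 1
#' off-diagonal entries when `include_diagonal = FALSE`.
#'
#' @param rankings Named list of `mcdm_ranking` objects (or bare rank
#'   vectors) over identical alternatives; at least 2.
#' @param include_diagonal Include the self-correlation in row means
#'   (default `TRUE`).
#' @return An object of class `rank_correlation`: list with `kendall`,
#'   `spearman` (M x M symmetric matrices, unit diagonal), `mean_kendall`,
#'   `mean_spearman` (named M-vectors).
#' @examples
#' rks <- rank_alternatives(labor_protection_matrix(), labor_protection_weights())
#' rank_correlation(rks)
#' @export
rank_correlation <- function(rankings, include_diagonal = TRUE) {
  rk <- extract_rank_matrix(rankings)
  m <- nrow(rk)
  kt <- sp <- diag(1, m)
  dimnames(kt) <- dimnames(sp) <- list(rownames(rk), rownames(rk))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      kt[i, j] <- kt[j, i] <- kendall_tau(rk[i, ], rk[j, ])
      sp[i, j] <- sp[j, i] <- spearman_rho(rk[i, ], rk[j, ])
    }
  }
  mean_fun <- if (include_diagonal) {
    rowMeans
  } else {
    function(x) (rowSums(x) - 1) / (ncol(x) - 1)
  }
  structure(list(kendall = kt, spearman = sp,
                 mean_kendall = mean_fun(kt), mean_spearman = mean_fun(sp),
                 include_diagonal = include_diagonal),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, digits = 3, ...) {
  cat("Kendall tau (row means ",
      if (x$include_diagonal) "incl." else "excl.", " diagonal)\n", sep = "")
  print(round(cbind(x$kendall, mean = x$mean_kendall), digits), ...)
  cat("Spearman rho\n")
  print(round(cbind(x$spearman, mean = x$mean_spearman), digits), ...)
  invisible(x)
}

# Accepts a named list of mcdm_rankings or rank vectors; returns an
# M x n matrix of ranks with aligned alternative columns.
extract_rank_matrix <- function(rankings) {
  if (is.matrix(rankings)) return(rankings)
  if (!is.list(rankings) || length(rankings) < 1L) {
    stop("need a non-empty list of rankings", call. = FALSE)
  }
  rows <- lapply(rankings, function(r) {
    if (inherits(r, "mcdm_ranking")) r$ranks else r
  })
  alts <- names(rows[[1L]])
  rk <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(names(r)) || is.null(alts)) {
      if (length(r) != length(rows[[1L]])) {
        stop("rankings cover different numbers of alternatives", call. = FALSE)
      }
      return(as.numeric(r))
    }
    if (!setequal(names(r), alts)) {
      stop("rankings cover different alternative sets", call. = FALSE)
    }
    as.numeric(r[alts])
  }))
  colnames(rk) <- alts
  if (is.null(names(rankings))) {
    rownames(rk) <- paste0("ranking", seq_along(rankings))
  } else {
    rownames(rk) <- names(rankings)
  }
  rk
}
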