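#' Borda scores across rankings
#'
#' Each ranking source awards an alternative `n - rank` points; totals are
#' summed over all M sources. With tie-free inputs the scores over all
#' alternatives always sum to `M * n(n-1)/2`.
#'
#' @param rankings Named list of `mcdm_ranking` objects or rank vectors over
#'   identical alternatives (M >= 1).
#' @return Named numeric vector of Borda scores (higher = more preferred).
#' @export
borda <- function(rankings) {
  rk <- extract_rank_matrix(rankings)
  colSums(ncol(rk) - rk)
}

#' Copeland scores across rankings
#'
#' For every ordered pair of alternatives, counts the rankings placing one
#' above the other; the pairwise outcome is +1 / 0 / -1 by majority, and an
#' alternative's Copeland score sums its outcomes against all rivals. Scores
#' always sum to zero.
#'
#' @inheritParams borda
#' @return Named numeric vector of Copeland scores.
#' @export
copeland <- function(rankings) {
  rk <- extract_rank_matrix(rankings)
  n <- ncol(rk)
  cs <- stats::setNames(numeric(n), colnames(rk))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        v_ij <- sum(rk[, i] < rk[, j])
        v_ji <- sum(rk[, j] < rk[, i])
        cs[i] <- cs[i] + sign(v_ij - v_ji)
      }
    }
  }
  cs
}

#' Consensus ranking with stability tie-breaks
#'
#' Aggregates a set of method rankings into a final consensus order: primary
#' key descending Borda score, ties broken by descending Copeland score, then
#' descending Stability Index, then alternative id. By default the Stability
#' Index is computed over the same rankings (methods as the scenario
#' universe) with cutoff `k`; a precomputed SI vector (e.g. from OAT
#' scenarios via [stability_index()]) can be supplied instead.
#'
#' @inheritParams borda
#' @param stability Optional named numeric SI vector aligned with the
#'   alternatives; computed from `rankings` with cutoff `k` when `NULL`.
#' @param k Top-k cutoff used when computing the default stability (default 1).
#' @return An object of class `consensus_report`: data frame with columns
#'   `alternative`, `borda`, `borda_rank`, `copeland`, `copeland_rank`,
#'   `stability`, `consensus_rank`, ordered by consensus rank.
#' @examples
#' rks <- rank_alternatives(labor_protection_matrix(), labor_protection_weights())
#' consensus_rank(rks)
#' @export
consensus_rank <- function(rankings, stability = NULL, k = 1) {
  rk <- extract_rank_matrix(rankings)
  b <- borda(rankings)
  cp <- copeland(rankings)
  alts <- colnames(rk)
  if (is.null(stability)) {
    stability <- stability_index(rankings, k = k)
  }
  si <- as.numeric(stability[alts])
  ord <- order(-b, -cp, -si, alts)
  final <- integer(length(alts))
  final[ord] <- seq_along(alts)
  out <- data.frame(alternative = alts,
                    borda = as.numeric(b),
                    borda_rank = as.numeric(ranks_from_scores(b)),
                    copeland = as.numeric(cp),
                    copeland_rank = as.numeric(ranks_from_scores(cp)),
                    stability = si,
                    consensus_rank = final,
                    row.names = NULL)
  structure(out[order(out$consensus_rank), ], class = c("consensus_report",
                                                        "data.frame"))
}

#' @export
print.consensus_report <- function(x, digits = 3, ...) {
  cat("Consensus ranking (Borda, Copeland ties, stability ties)\n")
  y <- as.data.frame(x)
  y$stability <- round(y$stability, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
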