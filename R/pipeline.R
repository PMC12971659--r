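#' Run the full prioritization pipeline
#'
#' Executes the complete decision-support chain on one problem: objective
#' weighting and Bonferroni fusion, MARCOS ranking, the five benchmark
#' rankers, rank-correlation analysis, one-at-a-time weight sensitivity with
#' rank-frequency tabulation and Stability Indices, and Borda/Copeland
#' consensus aggregation. Deterministic given its inputs.
#'
#' @param problem A [decision_problem]; defaults to the built-in labor
#'   protection case study.
#' @param weights `"auto"` to compute and fuse the four objective schemes,
#'   `"case"` for the published fused vector of the built-in case study, or a
#'   numeric weight vector.
#' @param methods Rankers to run (see [rank_alternatives()]); MARCOS is always
#'   included as the sensitivity ranker.
#' @param v,lambda_mix VIKOR and WASPAS parameters.
#' @param eps_levels OAT perturbation magnitudes.
#' @param policy Infeasible-scenario policy for [run_sensitivity()].
#' @param stability_k Top-k cutoff for Stability Indices.
#' @param include_oat If `TRUE`, fold the OAT scenario rankings' stability
#'   into the consensus tie-break instead of the method-universe SI.
#' @return An object of class `mcdm_report`: list with `problem`, `weights`
#'   (vector used), `weight_bundle` (when computed), `weight_pareto`,
#'   `rankings`, `correlation`, `scenarios`, `rank_frequency`,
#'   `stability_oat`, `stability_methods` and `consensus`.
#' @examples
#' report <- run_pipeline()
#' report$consensus
#' @export
run_pipeline <- function(problem = labor_protection_matrix(),
                         weights = "auto",
                         methods = c("marcos", "topsis", "vikor", "edas",
                                     "waspas", "promethee2"),
                         v = 0.5, lambda_mix = 0.5,
                         eps_levels = c(0.05, 0.10, 0.15),
                         policy = "include",
                         stability_k = 1,
                         include_oat = FALSE) {
  stopifnot(inherits(problem, "decision_problem"))
  bundle <- NULL
  if (is.character(weights)) {
    weights <- match.arg(weights, c("auto", "case"))
    if (weights == "auto") {
      bundle <- weight_bundle(problem)
      w <- bundle$fused
    } else {
      w <- labor_protection_weights()
    }
  } else {
    check_weights(weights, ncol(problem$scores))
    w <- stats::setNames(as.numeric(weights), colnames(problem$scores))
  }
  if (!"marcos" %in% methods) methods <- c("marcos", methods)
  rankings <- rank_alternatives(problem, w, methods = methods,
                                v = v, lambda_mix = lambda_mix)
  correlation <- rank_correlation(rankings)
  scenarios <- oat_scenarios(w, eps_levels)
  freq <- run_sensitivity(problem, scenarios, ranker = "marcos",
                          policy = policy)
  si_oat <- stability_index(freq, k = stability_k)
  si_methods <- stability_index(rankings, k = stability_k)
  consensus <- consensus_rank(
    rankings,
    stability = if (include_oat) si_oat else si_methods)
  structure(list(problem = problem,
                 weights = w,
                 weight_bundle = bundle,
                 weight_pareto = weight_pareto(w),
                 rankings = rankings,
                 correlation = correlation,
                 scenarios = scenarios,
                 rank_frequency = freq,
                 stability_oat = si_oat,
                 stability_methods = si_methods,
                 consensus = consensus),
            class = "mcdm_report")
}

#' @export
print.mcdm_report <- function(x, ...) {
  cat("MCDM prioritization report:", nrow(x$problem$scores), "alternatives,",
      ncol(x$problem$scores), "criteria\n")
  cat("Weights:", paste(sprintf("%s=%.4f", names(x$weights), x$weights),
                        collapse = " "), "\n")
  cat("Rankers:", paste(names(x$rankings), collapse = ", "), "\n\n")
  print(x$consensus)
  invisible(x)
}

report_as_list <- function(report) {
  rk <- extract_rank_matrix(report$rankings)
  list(
    problem = list(
      alternatives = rownames(report$problem$scores),
      criteria = colnames(report$problem$scores),
      scores = unname(apply(report$problem$scores, 1L, as.numeric,
                            simplify = FALSE)),
      directions = unname(report$problem$directions)),
    weights = as.list(report$weights),
    weight_bundle = if (!is.null(report$weight_bundle)) {
      lapply(unclass(report$weight_bundle), as.list)
    },
    weight_pareto = report$weight_pareto,
    scores = lapply(report$rankings, function(r) as.list(r$scores)),
    ranks = lapply(seq_len(nrow(rk)),
                   function(i) as.list(stats::setNames(rk[i, ], colnames(rk)))) |>
      stats::setNames(rownames(rk)),
    correlation = list(
      kendall = report$correlation$kendall,
      spearman = report$correlation$spearman,
      mean_kendall = as.list(report$correlation$mean_kendall),
      mean_spearman = as.list(report$correlation$mean_spearman)),
    sensitivity = list(
      n_scenarios = nrow(report$scenarios$weights),
      n_infeasible = sum(!report$scenarios$info$feasible),
      policy = report$rank_frequency$policy,
      counts = report$rank_frequency$counts,
      stability_oat = as.list(report$stability_oat),
      stability_methods = as.list(report$stability_methods)),
    consensus = as.data.frame(report$consensus)
  )
}

#' Write a pipeline report to disk
#'
#' `format = "json"` writes one schema-stable JSON file echoing the inputs and
#' every computed section; `format = "csv"` writes one CSV per stage
#' (decision matrix, weights, cumulative weight shares, per-method scores and
#' ranks, both correlation matrices, scenario table, rank frequencies,
#' consensus).
#'
#' @param report An `mcdm_report` from [run_pipeline()].
#' @param path Output file (json) or directory (csv).
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  stopifnot(inherits(report, "mcdm_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name, rn = FALSE) {
    f <- file.path(path, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = rn)
    files <<- c(files, f)
  }
  put(data.frame(alternative = rownames(report$problem$scores),
                 report$problem$scores, check.names = FALSE),
      "decision_matrix")
  wtab <- if (!is.null(report$weight_bundle)) {
    as.data.frame(do.call(rbind, lapply(report$weight_bundle, as.numeric)))
  } else {
    as.data.frame(rbind(fused = as.numeric(report$weights)))
  }
  colnames(wtab) <- names(report$weights)
  put(wtab, "weights", rn = TRUE)
  put(report$weight_pareto, "weight_pareto")
  rk <- extract_rank_matrix(report$rankings)
  sc <- do.call(rbind, lapply(report$rankings, function(r) r$scores))
  put(as.data.frame(sc), "method_scores", rn = TRUE)
  put(as.data.frame(rk), "method_ranks", rn = TRUE)
  put(as.data.frame(report$correlation$kendall), "kendall", rn = TRUE)
  put(as.data.frame(report$correlation$spearman), "spearman", rn = TRUE)
  put(cbind(report$scenarios$info,
            as.data.frame(report$scenarios$weights)), "scenarios")
  put(as.data.frame(report$rank_frequency$counts), "rank_frequency", rn = TRUE)
  put(as.data.frame(report$consensus), "consensus")
  invisible(files)
}
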