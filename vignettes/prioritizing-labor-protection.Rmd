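---
title: "Prioritizing labor protection measures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing labor protection measures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oshmcdm)
```

## The decision problem

Occupational safety planners routinely have to rank a handful of intervention
domains — engineering controls, administrative controls, personal protective
equipment (PPE), training programs, digital monitoring systems — against
criteria that pull in different directions: life-cycle cost, risk-reduction
effectiveness, regulatory compliance, worker acceptance, sustainability, ease
of implementation. oshmcdm implements one coherent pipeline for this class of
problem: objective weighting, compromise ranking, cross-method benchmarking,
sensitivity analysis and consensus aggregation.

The input is a `decision_problem`: an n × m matrix of strictly positive
scores with a benefit/cost flag per criterion. Positivity is a hard
precondition, checked at construction: the reciprocal-sum CILOS weights and
the weighted-product branch of WASPAS are undefined at zero, and a zero score
on a 1–9 expert scale would in any case indicate a data error. All-benefit is
the default direction (the safety-first convention in which every criterion
is phrased so that more is better); the cost branch (min/x normalization,
mirrored ideals) is implemented and tested on synthetic data but is not
exercised by the shipped case study.

Normalization is x/max for benefit and min/x for cost columns, mapping every
entry into (0, 1] with each column's best alternative at 1. It is applied
even when all scores already share a uniform scale, so the ideal/anti-ideal
benchmarks of MARCOS are always expressed on the same footing.

## Objective weighting

Four schemes are computed on the raw matrix (one exception below), each
capturing a different notion of "importance carried by the data":

* **Entropy** — dispersion of column proportions. A criterion scored almost
  identically across alternatives has entropy near 1 and weight near 0.
* **CRITIC** — standard deviation times summed conflict `(1 − correlation)`
  with all criteria. The sd convention (sample vs population) cancels in the
  normalization; both are exposed and tested to coincide.
* **MEREC variant** (`variant = "linear"`) — removal effect of each criterion
  on equal-coefficient row means of the *normalized* matrix. With the
  coefficient 1/m kept fixed when a term is dropped, the removal effect
  collapses in closed form to `r_ij/m`, so weights are proportional to the
  normalized column sums. The classical logarithmic MEREC is available as
  `variant = "logarithmic"`; the two are different methods and the linear
  form is the package default because it is the formulation the shipped case
  study's weight table follows. This is the only scheme computed on the
  normalized rather than the raw matrix — required to reproduce that table,
  and flagged here deliberately.
* **CILOS variant** — weights proportional to the reciprocal mass
  `T_j = Σ_i 1/x_ij` of the raw columns. This is a simplification of the
  classical CILOS impact-loss construction (which builds a square loss matrix
  from criterion-wise winners); the classical form is out of scope.

The four vectors are fused with the Bonferroni mean of orders p = q = 1,
`BM_j = sqrt( Σ_{k≠l} w_j^(k) w_j^(l) / (K(K−1)) )`, then renormalized.
Averaging pairwise products rewards criteria on which schemes agree and damps
single-scheme outliers; fusing identical vectors returns them unchanged. On
the case study this fusion lands within 0.02 of the published fused vector
with the identical criterion rank order, but not equal to the fourth decimal:
the case study's exact fusion arithmetic is not recoverable from its stated
operator, so the published vector ships verbatim as
`labor_protection_weights()` and all exact downstream reproduction uses it.

```{r}
weight_bundle(labor_protection_matrix())
```

## MARCOS

The weighted normalized matrix is extended with anti-ideal and ideal rows
(columnwise minima and maxima of the normalized values — observed bounds, not
theoretical scale bounds), summed to row scores Q, and mapped through the
benchmark ratios `k⁺ = Q/Q⁺`, `k⁻ = Q/Q⁻` into the compromise utility

U = (k⁺ + k⁻) / (1 + (1 − f⁺)/f⁺ + (1 − f⁻)/f⁻),  f⁺ = k⁻/(k⁺+k⁻), f⁻ = k⁺/(k⁺+k⁻).

U is strictly increasing in Q at fixed references, so MARCOS preserves the
weighted-sum order within a run; what the utility adds is an interpretable
position between the anti-ideal and ideal anchors (the case study's utilities
run from 0.4487 at the anti-ideal to 0.8443 at the ideal). A naive ratio
`k⁺/k⁻` would be constant across alternatives (it equals Q⁻/Q⁺) and cannot
rank anything — the compromise function above is the standard, non-degenerate
form and is the one this package implements.

```{r}
marcos(labor_protection_matrix(), labor_protection_weights())
```

## Benchmark rankers

Method variants were fixed once, to the most common textbook forms: TOPSIS
with vector (root-sum-square) normalization; VIKOR with linear normalization
and compromise coefficient v = 0.5, reporting the full Q order without the
acceptable-advantage screening (a single complete ranking is wanted);
EDAS with the arithmetic-mean average solution; WASPAS with λ = 0.5 on the
max-normalized matrix (λ = 1 reduces exactly to the MARCOS weighted-sum
column); PROMETHEE-II with the usual 0/1 preference criterion. All scores are
stored higher-is-better (VIKOR's Q is negated internally, raw Q kept in
`details`), so correlation, sensitivity and consensus code never branches on
orientation. Ranks are 1-based, 1 = best, ties sharing the average rank.

## Agreement and its one unusual convention

Kendall's τ is tau-a (denominator n(n−1)/2, no tie correction — the shipped
rankings are tie-free) and Spearman's ρ uses the 6Σd² difference formula,
falling back to the moment correlation of ranks under ties. One convention
deserves a flag: per-method mean correlations are computed **including the
diagonal self-correlation of 1** by default, because that is the convention
the case study's summary row follows (VIKOR's mean τ of
(0.2+0.4+1+0.4+0.4+0.2)/6 = 0.433 is only obtained diagonal-inclusively).
`rank_correlation(..., include_diagonal = FALSE)` gives the conventional
off-diagonal mean.

## Sensitivity analysis

One-at-a-time perturbation: `w'_h = w_h ± ε`, with the mass redistributed
evenly over the other m − 1 criteria, for ε ∈ {0.05, 0.10, 0.15} by default —
6 criteria × 3 levels × 2 signs = 36 scenarios on the case study. Large
negative perturbations can drive a small focal weight negative (three case
study scenarios: C2, C3, C4 at −0.15). Three policies are provided:
`include` (default — use the vector as-is, keeping the scenario universe
complete), `skip` (drop infeasible scenarios) and `clamp` (floor at zero and
renormalize). `include` is the default because the case study's own
frequency tabulation is over all 36 scenarios even though it declares 33
feasible.

A reproduction caveat, stated plainly: the case study's published interior
rank-frequency counts are not recoverable from this scheme under any of the
three policies (its table shows PPE at rank 5 and digital monitoring at
rank 1 in a few scenarios, placements that no ±0.15 perturbation of the fused
weights can produce). The package reproduces the scenario design (36/3), the
row sums, the administrative-controls row and its Top-2 stability of 1.0
exactly; the remaining interior counts are the package's own faithful
computation, and the corresponding cross-check in the test suite is expected
to disagree with the published table and is kept failing rather than relaxed.

The Stability Index `SI_i(k)` is the fraction of scenarios in which
alternative i ranks within the top k; it is non-decreasing in k and equals 1
at k = n. Two scenario universes are supported — the OAT scenarios and the
method rankings themselves — because both denominators are useful summaries
(36 and 6 respectively on the case study).

## Consensus

Borda awards `n − rank` per source; Copeland scores pairwise majority wins
(+1/0/−1). The final order sorts by Borda, breaking ties by Copeland, then
Stability Index, then alternative id. On the case study the six method
rankings alone reproduce the published aggregation (Borda 22, 18, 14, 4, 2;
Copeland +4, +2, 0, −2, −4; final order A3 > A2 > A4 > A1 > A5); OAT-scenario
stability can be folded into the tie-break via
`run_pipeline(include_oat = TRUE)`.

```{r}
consensus_rank(rank_alternatives(labor_protection_matrix(),
                                 labor_protection_weights()))
```

## Synthetic data

`synthetic_problem()` draws integer scores uniformly on a bounded scale
(default 1–9), emulating panel-averaged expert ratings only in range and
positivity. It makes no attempt to model inter-criterion correlation,
expert-panel averaging (which yields non-integer scores), or the near-tie
structure of real alternatives. Property tests built on it therefore
establish algebraic invariants — weight normalization, sd-convention
invariance, removal-oracle equivalence, Borda conservation, Copeland zero-sum
— not behavior on realistic preference structures; the case-study fixtures
carry that burden.

## Numerical choices and problem sizes

Tolerances: weight vectors must sum to 1 within 1e-9; published 4-decimal
values are matched within 5e-4; the fusion is matched within 0.02 (see
above). Ties in any ranking share the average rank, and fractional tied ranks
are ceiled when tabulated into integer rank bins. Degenerate inputs fail
loudly: all-constant matrices are rejected by entropy (no information) and
VIKOR (zero ranges), constant single columns by CRITIC (undefined
correlation). Test and example problems are small by nature (n ≤ 50, m ≤ 10);
every routine is O(n·m) to O(n²·m), so the full pipeline runs in well under a
second and the entire test suite in seconds on one CPU.

## Known limitations

* The classical CILOS impact-loss matrix and logarithmic-MEREC defaults are
  not implemented / not default, by design; the package follows its case
  study's formulations and says so where they deviate.
* The Bonferroni fusion matches the published fused vector only to 0.02
  (exact arithmetic unrecoverable); near-ties in the tail of a ranking (A1/A5
  under TOPSIS/EDAS on the case study) can swap between the computed and the
  published weights.
* PROMETHEE-II supports only the usual criterion; VIKOR's compromise-set
  conditions are intentionally omitted.
* Subjective weighting (AHP, BWM), fuzzy/interval extensions and multi-expert
  score aggregation are out of scope — the package starts from an already
  aggregated score matrix.
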