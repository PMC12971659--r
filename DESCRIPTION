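Package: oshmcdm
Title: Multi-Criteria Prioritization of Labor Protection Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated multi-criteria decision-making (MCDM) toolkit for
    prioritizing occupational safety and health interventions. Computes
    objective criterion weights (Entropy, CRITIC, a removal-effect MEREC
    variant and a reciprocal-sum CILOS variant), fuses them with a Bonferroni
    mean, ranks alternatives with MARCOS against ideal and anti-ideal
    reference profiles, benchmarks the ranking with TOPSIS, VIKOR, EDAS,
    WASPAS and PROMETHEE-II, and validates robustness through Kendall and
    Spearman rank correlation, one-at-a-time weight sensitivity analysis,
    Borda and Copeland consensus aggregation and a top-k Stability Index.
    Ships a worked case study of five labor protection measures scored on six
    criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
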