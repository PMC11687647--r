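Package: zipfadapt
Title: Least-Effort Adaptation Analysis for Phrase-Prediction Query Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether users of a phrase-prediction
    (autocomplete) system adapt their queries toward a Pareto-optimal
    trade-off between conciseness (query length) and distinctiveness
    (rank of the selected label), in the spirit of Zipf's principle of
    least effort. Provides a deterministic completion engine over a
    terminology with synonyms, a seeded agent-based simulator of
    interaction logs with Zipf-distributed label popularity, log
    enrichment with rank, query length and user-label seniority,
    per-label Pareto fronts and distance-to-front trajectories with
    Savitzky-Golay smoothing, tracking of medical-idiom (acronym and
    abbreviation) usage across experience levels, and rank-frequency
    power-law fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
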