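# Shared fixtures, built in code.

# Toy terminology in the spirit of the completion tool's documented use
# cases ("avc" as a registered synonym of the stroke label).
fig_terminology <- function() {
  terminology(data.frame(
    label_id = c(2477L, 4578L, 10598L, 847L, 15L),
    canonical_text = c(
      "Accident vasculaire cérébral ischémique",
      "Diabète de Type 2",
      "Douleur rétrosternale",
      "Infection des voies respiratoires supérieures",
      "Hypertension artérielle"
    ),
    synonyms = c("avc", "", "drs", "", "hta")
  ))
}

# Independent brute-force completion oracle: applies the match predicate
# (word-prefix OR substring, on every normalised variant) label by label,
# without any of the index structures complete_query() uses.
brute_force_candidates <- function(trm, query) {
  q <- normalize_text(query)
  toks <- strsplit(q, " ", fixed = TRUE)[[1]]
  hits <- integer(0)
  for (i in seq_len(nrow(trm$labels))) {
    variants <- normalize_text(c(trm$labels$canonical_text[i],
                                 trm$labels$synonyms[[i]]))
    variants <- variants[nzchar(variants)]
    ok <- any(vapply(variants, function(v) {
      words <- strsplit(v, " ", fixed = TRUE)[[1]]
      wp <- all(vapply(toks, function(tk) any(startsWith(words, tk)),
                       logical(1)))
      wp || grepl(q, v, fixed = TRUE)
    }, logical(1)))
    if (ok) hits <- c(hits, trm$labels$label_id[i])
  }
  hits
}

# O(n^2) brute-force Pareto front oracle on (k, j) pairs.
brute_force_front <- function(k, j) {
  pts <- unique(data.frame(k = k, j = j))
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts$k <= pts$k[i] & pts$j <= pts$j[i] &
           (pts$k < pts$k[i] | pts$j < pts$j[i]))
  }, logical(1))
  pts[keep, , drop = FALSE]
}

# The reference simulation study shared by the end-to-end convergence,
# objective-decomposition and idiom tests: 200 users, 300 labels, 50,000
# events, Zipf exponent 1, five seeds, with a matched no-adaptation run
# per seed. Computed lazily once per test session.
.study_env <- new.env(parent = emptyenv())

study_runs <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.study_env[[key]])) return(.study_env[[key]])
  runs <- lapply(seeds, function(sd) {
    trm <- generate_terminology(300, seed = sd)
    lex <- generate_idiom_lexicon(trm, seed = sd)
    log <- simulate_log(simulation_config(seed = sd), trm, lex)
    enr <- enrich_log(log, trm)
    dst <- annotate_distance(enr, pareto_fronts(enr, trm))
    flt <- consistency_filter(dst, 20)
    nul_log <- simulate_log(simulation_config(seed = sd, adaptation = FALSE),
                            trm, lex)
    nenr <- enrich_log(nul_log, trm)
    nul <- annotate_distance(nenr, pareto_fronts(nenr, trm))
    list(
      dist = curve_by_seniority(flt, "distance", S_max = 20),
      qlen = curve_by_seniority(flt, "qlen", S_max = 20),
      rank = curve_by_seniority(flt, "rank", S_max = 20),
      idiom = idiom_proportion_by_seniority(enr, lex, 15),
      null_ci = trend_bootstrap_ci(consistency_filter(nul, 20), "distance",
                                   S_max = 20, B = 200)
    )
  })
  .study_env[[key]] <- runs
  runs
}
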