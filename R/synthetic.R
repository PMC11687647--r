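# Bundled vocabulary for terminology generation, mirroring the structure of
# a clinical problem list: every label is a head noun (the pathology or
# finding) followed by one to three modifiers (site, cause, severity).
# Because many labels share a head noun, short novice queries (a stem of
# the head word) are ambiguous and poorly ranked, while two-token queries
# (head prefix + modifier prefix) are distinctive — the trade-off the
# analyses are designed to detect. Head-noun initials repeat, so acronyms
# built from word initials collide across labels, emulating the ambiguity
# of real medical acronyms (one short expression, many expansions).
.head_pool <- c(
  "douleur", "infection", "syndrome", "insuffisance", "fracture",
  "tumeur", "maladie", "hypertension", "hémorragie", "accident",
  "embolie", "sténose", "abcès", "anémie", "carcinome",
  "contusion", "plaie", "luxation", "migraine", "thrombose",
  "pneumonie", "gastrite", "otite", "hernie", "arthrose", "hépatite"
)
.modifier_pool <- c(
  "artérielle", "aiguë", "chronique", "sévère", "pulmonaire",
  "cardiaque", "cérébrale", "ischémique", "bactérienne", "virale",
  "rénale", "respiratoire", "biliaire", "lombaire", "thoracique",
  "veineuse", "périphérique", "obstructive", "intestinale", "bénigne",
  "rétrosternale", "fébrile", "décompensée", "abdominale", "vasculaire",
  "hépatique", "gauche", "droite", "bilatérale", "récidivante",
  "post-opératoire", "traumatique", "infectieuse", "inflammatoire",
  "dégénérative", "congénitale", "métabolique", "neurologique",
  "cutanée", "osseuse", "articulaire", "musculaire", "digestive",
  "urinaire", "pelvienne", "cervicale", "dorsale", "faciale",
  "oculaire", "auriculaire", "nasale", "buccale", "dentaire",
  "mammaire", "ovarienne", "prostatique", "testiculaire", "inguinale",
  "ombilicale", "diaphragmatique", "pleurale", "péricardique",
  "méningée", "médullaire", "radiale", "cubitale", "fémorale",
  "tibiale", "humérale", "claviculaire"
)

#' Acronym of a multi-word expression
#'
#' The initials rule used throughout the generator: the acronym of a label
#' text is the concatenation of the first letters of its normalised words
#' ("accident vasculaire cérébral" gives "avc").
#'
#' @param text Character vector of label texts.
#' @param alph The [alphabet()].
#' @return Character vector of acronyms (empty string for empty input).
#' @export
acronym_of <- function(text, alph = alphabet()) {
  vapply(strsplit(normalize_text(text, alph), " ", fixed = TRUE),
         function(w) paste(substr(w, 1, 1), collapse = ""), character(1))
}

#' Generate a synthetic terminology
#'
#' Builds a closed list of labels shaped like clinical problem-list
#' entries: a head noun drawn from a small pool of pathologies/findings
#' followed by one to three modifiers (site, cause, severity). A
#' configurable fraction of the labels receive their acronym (word
#' initials) as a registered synonym, emulating terminologies where common
#' acronyms such as "avc" are searchable synonyms of the full label.
#' Deterministic given `seed`.
#'
#' @param n_labels Number of labels (at least 1).
#' @param seed Integer seed.
#' @param acronym_frac Fraction of labels whose acronym is added as a
#'   synonym (default 0.2).
#' @param head_pool,modifier_pool Word pools for the leading head noun and
#'   the following modifiers.
#' @param alph The [alphabet()].
#' @return A [terminology()]. Labels get ids `1..n_labels`.
#' @export
generate_terminology <- function(n_labels, seed = 1L, acronym_frac = 0.2,
                                 head_pool = .head_pool,
                                 modifier_pool = .modifier_pool,
                                 alph = alphabet()) {
  if (length(n_labels) != 1L || is.na(n_labels) || n_labels < 1) {
    stop("n_labels must be a positive integer", call. = FALSE)
  }
  n_labels <- as.integer(n_labels)
  withr::local_seed(seed)
  texts <- character(0)
  guard <- 0L
  while (length(texts) < n_labels) {
    nm <- sample(1:3, n_labels, replace = TRUE, prob = c(0.5, 0.38, 0.12))
    new <- vapply(nm, function(k) {
      paste(c(sample(head_pool, 1), sample(modifier_pool, k)), collapse = " ")
    }, character(1))
    texts <- unique(c(texts, new))
    guard <- guard + 1L
    if (guard > 100L) stop("could not generate enough distinct labels", call. = FALSE)
  }
  texts <- texts[seq_len(n_labels)]
  acr <- acronym_of(texts, alph)
  has_syn <- nchar(acr) >= 2 & stats::runif(n_labels) < acronym_frac
  syn <- ifelse(has_syn, acr, "")
  terminology(
    data.frame(label_id = seq_len(n_labels), canonical_text = texts,
               synonyms = syn, stringsAsFactors = FALSE),
    alph
  )
}

#' Idiom lexicon
#'
#' The set of jargon expressions (acronyms and abbreviations) whose usage is
#' tracked across experience levels. Expressions are normalised and
#' de-duplicated; empty strings are rejected.
#'
#' @param expressions Character vector.
#' @param alph The [alphabet()].
#' @return Object of class `ppd_idiom_lexicon` (a normalised character set).
#' @export
idiom_lexicon <- function(expressions, alph = alphabet()) {
  ex <- unique(normalize_text(expressions, alph))
  ex <- ex[nzchar(ex)]
  if (length(ex) == 0) stop("lexicon must contain at least one expression", call. = FALSE)
  structure(sort(ex), class = "ppd_idiom_lexicon")
}

#' @export
print.ppd_idiom_lexicon <- function(x, ...) {
  cat("<idiom lexicon> ", length(x), " expressions\n", sep = "")
  invisible(x)
}

#' Read or write an idiom lexicon (plain text, one expression per line)
#'
#' @param path File path.
#' @param alph The [alphabet()].
#' @export
read_idiom_lexicon <- function(path, alph = alphabet()) {
  idiom_lexicon(readLines(path, encoding = "UTF-8", warn = FALSE), alph)
}

#' @rdname read_idiom_lexicon
#' @param lexicon A `ppd_idiom_lexicon`.
#' @export
write_idiom_lexicon <- function(lexicon, path) {
  writeLines(unclass(lexicon), path, useBytes = TRUE)
  invisible(path)
}

#' Generate the idiom lexicon paired with a synthetic terminology
#'
#' Two kinds of jargon expressions are emitted, mirroring the mix of
#' acronyms and abbreviations seen in clinical queries: (a) every acronym
#' registered as a synonym in the terminology, and (b) for a fraction of
#' labels, a truncation of the first word (its first `stem_len` letters) —
#' the "abbreviation" habit of typing a short stem of the salient word.
#' Deterministic given `seed`.
#'
#' @param trm A generated [terminology()].
#' @param seed Integer seed.
#' @param stem_frac Fraction of labels contributing a first-word stem
#'   (default 0.4).
#' @param stem_len Stem length in characters (default 3).
#' @return A [idiom_lexicon()].
#' @export
generate_idiom_lexicon <- function(trm, seed = 1L, stem_frac = 0.4, stem_len = 3L) {
  stopifnot(inherits(trm, "ppd_terminology"))
  withr::local_seed(seed + 1L)
  acr <- unlist(trm$labels$synonyms, use.names = FALSE)
  first_word <- vapply(strsplit(trm$labels$canonical_norm, " ", fixed = TRUE),
                       `[`, character(1), 1)
  pick <- stats::runif(nrow(trm$labels)) < stem_frac
  stems <- substr(first_word[pick], 1, stem_len)
  stems <- stems[nchar(stems) >= 2]
  idiom_lexicon(c(acr, stems), trm$alphabet)
}

#' Zipf-distributed label selection weights
#'
#' Popularity weights for labels: the weight of the rank-`r` label is
#' proportional to `r^(-s)`, normalised to sum to one. Selected-label
#' frequencies in large interaction logs empirically follow such a power
#' law; `s` is its exponent.
#'
#' @param n_labels Number of labels.
#' @param s Power-law exponent, strictly positive.
#' @return Numeric vector of probabilities summing to 1.
#' @examples
#' sample_label_weights(2, 1) # c(2/3, 1/3)
#' @export
sample_label_weights <- function(n_labels, s) {
  if (length(s) != 1L || is.na(s) || s <= 0) {
    stop("zipf exponent s must be > 0", call. = FALSE)
  }
  if (n_labels < 1) stop("n_labels must be >= 1", call. = FALSE)
  w <- seq_len(n_labels)^(-s)
  w / sum(w)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the interaction-log simulator.
#' Defaults reproduce the reference study conditions used throughout the
#' package's convergence analyses: 200 users, 300 labels, 50,000 events,
#' Zipf exponent 1, exploration schedule epsilon(s) = 0.8 * 0.85^(s-1)
#' (naive behaviour fading over roughly the first five selections), idioms
#' used for 80% of first selections.
#'
#' @param n_users,n_labels,n_events Positive integers.
#' @param zipf_s Power-law exponent of label popularity (> 0).
#' @param epsilon0 Exploration probability at the second selection (0..1).
#' @param decay Multiplicative decay of exploration per seniority level
#'   (0 < decay <= 1).
#' @param idiom_start_prob Probability that a pair's first query is the
#'   label's idiom, when one is feasible (0..1).
#' @param adaptation Logical: when `FALSE`, every pair keeps its first
#'   query forever (the null model).
#' @param adoption_rule `"pareto"` (adopt a candidate that weakly dominates
#'   the current best; exact objective ties switch with probability 1/2) or
#'   `"scalarized"` (adopt when the weighted sum improves strictly).
#' @param scalar_weight Weight of query length in the scalarized rule.
#' @param J Suggestion-list cap of the completion engine.
#' @param n_candidates Candidates sampled per exploration step.
#' @param seed Integer root seed for the whole simulation.
#' @return A validated list of class `ppd_sim_config`.
#' @export
simulation_config <- function(n_users = 200L, n_labels = 300L,
                              n_events = 50000L, zipf_s = 1,
                              epsilon0 = 0.8, decay = 0.85,
                              idiom_start_prob = 0.8, adaptation = TRUE,
                              adoption_rule = c("pareto", "scalarized"),
                              scalar_weight = 0.5, J = 30L,
                              n_candidates = 5L, seed = 1L) {
  adoption_rule <- match.arg(adoption_rule)
  cfg <- list(
    n_users = as.integer(n_users), n_labels = as.integer(n_labels),
    n_events = as.integer(n_events), zipf_s = zipf_s,
    epsilon0 = epsilon0, decay = decay,
    idiom_start_prob = idiom_start_prob, adaptation = isTRUE(adaptation),
    adoption_rule = adoption_rule, scalar_weight = scalar_weight,
    J = as.integer(J), n_candidates = as.integer(n_candidates),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_users >= 1, n_labels >= 1, n_events >= 1, zipf_s > 0,
              epsilon0 >= 0, epsilon0 <= 1, decay > 0, decay <= 1,
              idiom_start_prob >= 0, idiom_start_prob <= 1,
              scalar_weight >= 0, scalar_weight <= 1,
              J >= 1, n_candidates >= 1)
  })
  structure(cfg, class = "ppd_sim_config")
}

#' Evaluate the two objectives of a query for a target label
#'
#' @param trm A [terminology()].
#' @param query Query string.
#' @param label_id Target label.
#' @param J Suggestion-list cap.
#' @return List with `k` (normalised query length) and `j` (rank of the
#'   label, `NA` when infeasible).
#' @export
evaluate_objectives <- function(trm, query, label_id, J = 30L) {
  r <- rank_of_label(trm, label_id, query, J)
  list(k = nchar(normalize_text(query, trm$alphabet)), j = r)
}

# Candidate query pool for one label: canonical prefixes, the acronym, and
# first-token-prefix + second-token-prefix combinations. Only feasible
# candidates (label reachable within top J) are kept. No RNG used.
label_candidate_pool <- function(trm, row, J) {
  text <- trm$labels$canonical_norm[row]
  lid <- trm$labels$label_id[row]
  words <- strsplit(text, " ", fixed = TRUE)[[1]]
  cand <- character(0)
  pref <- unique(trimws(substring(text, 1, 2:min(nchar(text), 14L))))
  cand <- c(cand, pref)
  if (length(words) >= 2) {
    cand <- c(cand, paste(substr(words[1], 1, 1), collapse = ""))
    acr <- paste(substr(words, 1, 1), collapse = "")
    cuts1 <- unique(pmin(c(1L, 2L, 3L, nchar(words[1])), nchar(words[1])))
    cuts2 <- unique(pmin(c(1L, 2L, 3L, nchar(words[2])), nchar(words[2])))
    combo <- as.vector(outer(substring(words[1], 1, cuts1),
                             substring(words[2], 1, cuts2), paste))
    # standalone prefixes of the distinctive later words, as users also
    # type the modifier rather than the (shared) head noun
    mods <- words[-1]
    mod_pref <- unlist(lapply(mods, function(w) {
      substring(w, 1, unique(pmin(c(2L, 3L, 4L, nchar(w)), nchar(w))))
    }), use.names = FALSE)
    cand <- c(cand, acr, combo, mod_pref)
  }
  cand <- unique(cand[nzchar(cand)])
  j <- vapply(cand, function(q) {
    r <- match(lid, complete_query(trm, q, J))
    if (is.na(r)) NA_integer_ else as.integer(r)
  }, integer(1), USE.NAMES = FALSE)
  keep <- !is.na(j)
  p <- list(query = cand[keep], k = nchar(cand[keep]), j = j[keep],
            is_prefix = cand[keep] %in% pref)
  # Pareto-efficiency of each candidate within the pool
  p$efficient <- !vapply(seq_along(p$query), function(i) {
    any(p$k <= p$k[i] & p$j <= p$j[i] & (p$k < p$k[i] | p$j < p$j[i]))
  }, logical(1))
  p
}

#' Simulate a seeded interaction log
#'
#' Agent-based generator of raw interaction records. Each event draws a
#' label by Zipf popularity and a user uniformly. At a pair's first
#' selection the agent types, with probability `idiom_start_prob`, the
#' label's jargon idiom (acronym or first-word stem, when feasible),
#' otherwise a short feasible prefix of the label text (2-5 characters):
#' novice behaviour minimises typing at the cost of ambiguous, poorly
#' ranked suggestions.
#' At each later selection the agent explores with probability
#' `epsilon0 * decay^(seniority - 1)`: it samples a few candidate queries
#' (canonical prefixes, the acronym, two-token prefix combinations),
#' evaluates their objectives against the completion engine, and adopts a
#' candidate that Pareto-dominates its current best query (objective ties
#' switch with probability 1/2); otherwise it reuses its best-known query.
#' With `adaptation = FALSE` the first query is kept forever. Only feasible
#' queries — those that surface the target label within the top `J`
#' suggestions — are ever submitted. Timestamps are strictly increasing
#' integer ticks; the whole log is reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param trm The [terminology()] (defaults to a generated one with
#'   `config$n_labels` labels).
#' @param lexicon The [idiom_lexicon()] paired with `trm`.
#' @return Tibble with columns `user`, `query`, `label_id`, `timestamp`.
#' @export
simulate_log <- function(config = simulation_config(),
                         trm = NULL, lexicon = NULL) {
  stopifnot(inherits(config, "ppd_sim_config"))
  if (is.null(trm)) trm <- generate_terminology(config$n_labels, config$seed)
  if (is.null(lexicon)) lexicon <- generate_idiom_lexicon(trm, config$seed)
  stopifnot(inherits(trm, "ppd_terminology"), inherits(lexicon, "ppd_idiom_lexicon"))
  if (any(!nzchar(trm$labels$canonical_norm))) {
    stop("terminology contains a label with empty text", call. = FALSE)
  }
  n_lab <- nrow(trm$labels)
  J <- config$J
  withr::local_seed(config$seed)

  w <- sample_label_weights(n_lab, config$zipf_s)
  ev_label <- sample.int(n_lab, config$n_events, replace = TRUE, prob = w)
  ev_user <- sample.int(config$n_users, config$n_events, replace = TRUE)
  u_explore <- stats::runif(config$n_events)

  # per-label lazy structures ------------------------------------------------
  pools <- vector("list", n_lab)
  idioms <- rep(NA_character_, n_lab)   # feasible idiom query or NA
  idiom_done <- logical(n_lab)
  get_pool <- function(li) {
    p <- pools[[li]]
    if (is.null(p)) {
      p <- label_candidate_pool(trm, li, J)
      pools[[li]] <<- p
    }
    p
  }
  get_idiom <- function(li) {
    if (!idiom_done[li]) {
      idiom_done[li] <<- TRUE
      text <- trm$labels$canonical_norm[li]
      cands <- c(acronym_of(text), substr(strsplit(text, " ", fixed = TRUE)[[1]][1], 1, 3))
      cands <- cands[cands %in% unclass(lexicon)]
      for (q in cands) {
        r <- match(trm$labels$label_id[li], complete_query(trm, q, J))
        if (!is.na(r)) { idioms[li] <<- q; break }
      }
    }
    idioms[li]
  }

  # agent state: one slot per (user, label) pair, keyed on first occurrence
  pair_key <- paste0(ev_user, "\r", ev_label)
  pair_id <- match(pair_key, unique(pair_key))
  n_pairs <- max(pair_id)
  st_query <- character(n_pairs)
  st_k <- integer(n_pairs)
  st_j <- integer(n_pairs)
  st_sen <- integer(n_pairs)
  st_dom <- logical(n_pairs)   # is the current best dominated within the pool?
  is_dominated <- function(pool, k, j) {
    any(pool$k <= k & pool$j <= j & (pool$k < k | pool$j < j))
  }

  scalar <- config$adoption_rule == "scalarized"
  wgt <- config$scalar_weight
  queries <- character(config$n_events)

  for (e in seq_len(config$n_events)) {
    li <- ev_label[e]
    pid <- pair_id[e]
    s <- st_sen[pid] + 1L
    st_sen[pid] <- s
    if (s == 1L) {
      pool <- get_pool(li)
      idm <- get_idiom(li)
      if (!is.na(idm) && stats::runif(1) < config$idiom_start_prob) {
        q <- idm
        j <- match(trm$labels$label_id[li], complete_query(trm, q, J))
        st_query[pid] <- q; st_k[pid] <- nchar(q); st_j[pid] <- j
      } else {
        sel <- which(pool$is_prefix & pool$k >= 3L & pool$k <= 5L)
        if (length(sel) == 0) sel <- which(pool$is_prefix)
        if (length(sel) == 0) sel <- seq_along(pool$query)
        i <- sel[sample.int(length(sel), 1)]
        st_query[pid] <- pool$query[i]; st_k[pid] <- pool$k[i]; st_j[pid] <- pool$j[i]
      }
      st_dom[pid] <- is_dominated(pool, st_k[pid], st_j[pid])
    } else if (config$adaptation &&
               u_explore[e] < config$epsilon0 * config$decay^(s - 1)) {
      pool <- get_pool(li)
      m <- length(pool$query)
      if (m > 0) {
        take <- if (m <= config$n_candidates) seq_len(m) else
          sample.int(m, config$n_candidates)
        for (i in take) {
          ck <- pool$k[i]; cj <- pool$j[i]
          if (scalar) {
            if (wgt * ck + (1 - wgt) * cj <
                wgt * st_k[pid] + (1 - wgt) * st_j[pid]) {
              st_query[pid] <- pool$query[i]; st_k[pid] <- ck; st_j[pid] <- cj
            }
          } else if (ck <= st_k[pid] && cj <= st_j[pid]) {
            # weak dominance (exact objective ties switch half the time)
            if (ck < st_k[pid] || cj < st_j[pid] || stats::runif(1) < 0.5) {
              st_query[pid] <- pool$query[i]; st_k[pid] <- ck; st_j[pid] <- cj
              st_dom[pid] <- !pool$efficient[i]
            }
          } else if (st_dom[pid] && pool$efficient[i] &&
                     stats::runif(1) < 0.5) {
            # sideways escape: a dominated incumbent may be traded for a
            # Pareto-efficient candidate even when the two are incomparable
            st_query[pid] <- pool$query[i]; st_k[pid] <- ck; st_j[pid] <- cj
            st_dom[pid] <- FALSE
          }
        }
      }
    }
    queries[e] <- st_query[pid]
  }

  tibble::tibble(
    user = sprintf("u%04d", ev_user),
    query = queries,
    label_id = trm$labels$label_id[ev_label],
    timestamp = seq_len(config$n_events)
  )
}
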