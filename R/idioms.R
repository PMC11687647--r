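#' Is a query a jargon idiom?
#'
#' Membership is exact match after normalisation: idioms such as "hta" or
#' "avc" are used as standalone queries, so substring or prefix matching
#' would over-count. A prefix mode is available for sensitivity checks.
#'
#' @param query Character vector of queries.
#' @param lexicon An [idiom_lexicon()].
#' @param mode `"exact"` (default) or `"prefix"` (query is a prefix of an
#'   idiom or vice versa).
#' @param alph The [alphabet()].
#' @return Logical vector.
#' @examples
#' lex <- idiom_lexicon(c("hta", "avc"))
#' is_idiom(c("HTA ", "hypertension"), lex)
#' @export
is_idiom <- function(query, lexicon, mode = c("exact", "prefix"),
                     alph = alphabet()) {
  mode <- match.arg(mode)
  stopifnot(inherits(lexicon, "ppd_idiom_lexicon"))
  q <- normalize_text(query, alph)
  if (mode == "exact") {
    q %in% unclass(lexicon)
  } else {
    vapply(q, function(x) {
      nzchar(x) && any(startsWith(unclass(lexicon), x) |
                         startsWith(x, unclass(lexicon)))
    }, logical(1), USE.NAMES = FALSE)
  }
}

#' Labels selected at least once through an idiom query
#'
#' @param log Log with `query` and `label_id` columns.
#' @param lexicon An [idiom_lexicon()].
#' @param alph The [alphabet()].
#' @return Sorted vector of label ids.
#' @export
labels_with_idiom_queries <- function(log, lexicon, alph = alphabet()) {
  sort(unique(log$label_id[is_idiom(log$query, lexicon, alph = alph)]))
}

#' Idiom usage proportion by seniority level
#'
#' Restricts the log to labels associated with at least one idiom query,
#' then reports, per seniority level up to `S_cap`, the proportion of
#' records whose query is an idiom, together with the raw counts (so every
#' proportion can be recomputed independently) and the idiom activity
#' count. Levels with no records are absent (gaps).
#'
#' @param log Enriched log (needs `seniority`).
#' @param lexicon An [idiom_lexicon()].
#' @param S_cap Highest seniority level reported (default 15).
#' @param alph The [alphabet()].
#' @return Tibble with columns `level`, `n` (records), `n_idiom`,
#'   `proportion`.
#' @export
idiom_proportion_by_seniority <- function(log, lexicon, S_cap = 15L,
                                          alph = alphabet()) {
  stopifnot(is.data.frame(log), "seniority" %in% names(log))
  idm <- is_idiom(log$query, lexicon, alph = alph)
  keep_lab <- unique(log$label_id[idm])
  sel <- log$label_id %in% keep_lab & log$seniority <= S_cap
  if (!any(sel)) {
    return(tibble::tibble(level = integer(0), n = integer(0),
                          n_idiom = integer(0), proportion = numeric(0)))
  }
  lev <- log$seniority[sel]
  idm <- idm[sel]
  n <- tapply(idm, lev, length)
  ni <- tapply(idm, lev, sum)
  out <- tibble::tibble(
    level = as.integer(names(n)), n = as.integer(n),
    n_idiom = as.integer(ni), proportion = as.numeric(ni) / as.numeric(n)
  )
  out[order(out$level), , drop = FALSE]
}

#' Per-zone query statistics for one label
#'
#' A per-label case study in the style of the "hta" example: seniority
#' levels are partitioned into zones by cut points (`boundaries = c(5, 10)`
#' gives zones 1-5, 6-10, 11+), and within each zone the queries used to
#' select the label are tabulated with their counts, idiom status, and the
#' label's current rank under the completion engine for that query.
#'
#' @param log Enriched log.
#' @param label_id The studied label.
#' @param boundaries Strictly increasing seniority cut points.
#' @param trm The [terminology()] (for current ranks).
#' @param lexicon An [idiom_lexicon()].
#' @param J Suggestion-list cap.
#' @return Tibble with columns `zone`, `query`, `count`, `is_idiom`,
#'   `current_rank`; within each zone queries are sorted by count
#'   descending, ties lexicographic.
#' @export
query_case_study <- function(log, label_id, boundaries = c(5L, 10L),
                             trm = NULL, lexicon = NULL, J = 30L) {
  stopifnot(is.data.frame(log), "seniority" %in% names(log))
  if (!label_id %in% log$label_id) {
    stop("label ", label_id, " does not occur in the log", call. = FALSE)
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("zone boundaries must be strictly increasing", call. = FALSE)
  }
  sub <- log[log$label_id == label_id, , drop = FALSE]
  starts <- c(1, boundaries + 1)
  zone_names <- c(paste0(starts[-length(starts)], "-", boundaries),
                  paste0(starts[length(starts)], "+"))
  zone <- zone_names[findInterval(sub$seniority, starts)]
  qn <- normalize_text(sub$query)
  cnt <- as.data.frame(table(zone = zone, query = qn), stringsAsFactors = FALSE)
  cnt <- cnt[cnt$Freq > 0, , drop = FALSE]
  out <- tibble::tibble(
    zone = cnt$zone, query = cnt$query, count = as.integer(cnt$Freq),
    is_idiom = if (is.null(lexicon)) NA else is_idiom(cnt$query, lexicon),
    current_rank = if (is.null(trm)) NA_integer_ else
      vapply(cnt$query, function(q) {
        r <- rank_of_label(trm, label_id, q, J)
        if (is.na(r)) NA_integer_ else as.integer(r)
      }, integer(1), USE.NAMES = FALSE)
  )
  out <- out[order(match(out$zone, zone_names), -out$count, out$query), ,
             drop = FALSE]
  out
}

#' Most used idiom expressions
#'
#' Ranks idiom expressions by how often they occur as queries in the log
#' and reports, for each, the label most often selected through it (ties
#' broken by the smaller label id).
#'
#' @param log Log with `query` and `label_id`.
#' @param lexicon An [idiom_lexicon()].
#' @param n Number of expressions to return (default 30).
#' @param alph The [alphabet()].
#' @return Tibble with columns `expression`, `occurrences`, `top_label_id`,
#'   sorted by occurrences descending.
#' @export
top_idioms <- function(log, lexicon, n = 30L, alph = alphabet()) {
  stopifnot(n >= 1)
  qn <- normalize_text(log$query, alph)
  sel <- qn %in% unclass(lexicon)
  if (!any(sel)) {
    return(tibble::tibble(expression = character(0), occurrences = integer(0),
                          top_label_id = integer(0)))
  }
  df <- data.frame(expr = qn[sel], label_id = log$label_id[sel])
  occ <- table(df$expr)
  modal <- vapply(names(occ), function(e) {
    t <- table(df$label_id[df$expr == e])
    ids <- as.integer(names(t))
    ids[t == max(t)][1]  # names(t) sorted ascending: smallest id wins ties
  }, integer(1))
  out <- tibble::tibble(
    expression = names(occ), occurrences = as.integer(occ),
    top_label_id = as.integer(modal)
  )
  out <- out[order(-out$occurrences, out$expression), , drop = FALSE]
  utils::head(out, n)
}
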