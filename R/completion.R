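#' Run the phrase-prediction engine on one query
#'
#' A deterministic stand-in for an incremental completion engine: given a
#' typed partial query it returns a ranked, repetition-free list of label
#' ids. A label is a candidate when, on its normalised canonical text or on
#' any normalised synonym, either (a) every space-separated query token is a
#' prefix of some word of that text (word-prefix match), or (b) the whole
#' query is a contiguous substring of that text. Candidates are ordered by
#' match quality (exact equality with a canonical text or synonym beats a
#' word-prefix match, which beats a substring-only match), then by shorter
#' matched text, then by ascending label id, and the list is truncated to
#' the first `J` entries.
#'
#' The three contracts downstream analyses rely on are: determinism (a fixed
#' terminology and query always yield the same list), no repetition (a label
#' appears at most once), and incremental narrowing (extending the last
#' token of a query never adds new candidates).
#'
#' @param trm A [terminology()].
#' @param query Query string; must be non-empty after [normalize_text()].
#' @param J Suggestion-list cap (default 30).
#' @return Integer vector of label ids, best first, of length at most `J`.
#'   `attr(, "query_norm")` carries the normalised query.
#' @examples
#' trm <- terminology(data.frame(
#'   label_id = c(2477, 9),
#'   canonical_text = c("Accident vasculaire cérébral ischémique", "Avocat"),
#'   synonyms = c("avc", "")
#' ))
#' complete_query(trm, "avc")
#' @export
complete_query <- function(trm, query, J = 30L) {
  stopifnot(inherits(trm, "ppd_terminology"))
  if (length(J) != 1L || is.na(J) || J < 1) {
    stop("J must be a positive integer", call. = FALSE)
  }
  q <- normalize_text(query, trm$alphabet)
  if (!nzchar(q)) stop("query is empty after normalization", call. = FALSE)

  key <- paste0(J, "\r", q)
  hit <- trm$cache[[key]]
  if (!is.null(hit)) return(hit)

  # entry-level scores: 3 exact, 2 word-prefix, 1 substring-only
  score <- integer(length(trm$entry_text))
  sub <- grepl(q, trm$entry_text, fixed = TRUE)
  score[sub] <- 1L
  toks <- strsplit(q, " ", fixed = TRUE)[[1]]
  wp <- NULL
  for (tk in toks) {
    ent <- unique(trm$word_entry[startsWith(trm$word, tk)])
    wp <- if (is.null(wp)) ent else intersect(wp, ent)
    if (length(wp) == 0L) break
  }
  score[wp] <- 2L
  score[trm$entry_text == q] <- 3L

  cand <- which(score > 0L)
  if (length(cand) == 0L) {
    res <- integer(0)
  } else {
    # label score = best entry score; label tie-break length = shortest text
    # among its best-scoring entries
    lab <- trm$entry_label[cand]
    sc <- score[cand]
    nc <- trm$entry_nchar[cand]
    ord <- order(lab, -sc, nc)
    lab <- lab[ord]; sc <- sc[ord]; nc <- nc[ord]
    first <- !duplicated(lab)
    lab <- lab[first]; sc <- sc[first]; nc <- nc[first]
    ids <- trm$labels$label_id[lab]
    res <- ids[order(-sc, nc, ids)]
    if (length(res) > J) res <- res[seq_len(J)]
  }
  attr(res, "query_norm") <- q
  trm$cache[[key]] <- res
  res
}

#' Rank of a label in the suggestions for a query
#'
#' @inheritParams complete_query
#' @param label_id A label id present in the terminology.
#' @return The 1-based position of `label_id` in `complete_query(trm,
#'   query, J)`, or `NA_integer_` when the label is not suggested within the
#'   top `J`.
#' @examples
#' trm <- terminology(data.frame(label_id = 1, canonical_text = "douleur"))
#' rank_of_label(trm, 1, "dou")
#' @export
rank_of_label <- function(trm, label_id, query, J = 30L) {
  stopifnot(inherits(trm, "ppd_terminology"))
  if (!label_id %in% trm$labels$label_id) {
    stop("unknown label_id: ", label_id, call. = FALSE)
  }
  match(as.integer(label_id), complete_query(trm, query, J))
}

# Completion results for a batch of distinct queries, as one long table.
# Shared by rank annotation, the empirical query space and the simulator.
completion_table <- function(trm, queries, J = 30L) {
  queries <- unique(queries)
  res <- lapply(queries, function(q) complete_query(trm, q, J))
  n <- lengths(res)
  tibble::tibble(
    query = rep(queries, n),
    label_id = as.integer(unlist(res, use.names = FALSE)),
    rank = as.integer(unlist(lapply(n, seq_len), use.names = FALSE))
  )
}
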