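#' Query length
#'
#' The conciseness objective: the number of characters of the raw query,
#' spaces included. Queries must be non-empty.
#'
#' @param query Character vector of queries.
#' @return Integer vector of character counts.
#' @examples
#' qlen(c("diabet", "ac vas"))
#' @export
qlen <- function(query) {
  query <- as.character(query)
  if (any(is.na(query)) || any(!nzchar(query))) {
    stop("queries must be non-empty", call. = FALSE)
  }
  nchar(query)
}

#' Assign user-label seniority
#'
#' The user-label seniority of a record counts how many times that user has
#' selected that label so far: it is 1 at the first interaction of a
#' (user, label) pair and increases by 1 each time the same user selects
#' the same label again. Records are ordered by timestamp; ties keep the
#' stable input order. An `initial` table can seed the counters, for logs
#' that are continuations of an earlier observation window.
#'
#' @param log A data frame with columns `user`, `query`, `label_id`,
#'   `timestamp` (any orderable scalar).
#' @param initial Optional data frame with columns `user`, `label_id`,
#'   `start` giving the seniority of each pair's first record in `log`
#'   (default 1 for every pair).
#' @return The log, sorted by timestamp (stable), with integer columns
#'   `qlen` and `seniority` added.
#' @examples
#' log <- data.frame(user = "u", query = c("d", "di", "dia"),
#'                   label_id = 1L, timestamp = 1:3)
#' assign_seniority(log)$seniority
#' @export
assign_seniority <- function(log, initial = NULL) {
  stopifnot(is.data.frame(log))
  need <- c("user", "query", "label_id", "timestamp")
  if (!all(need %in% names(log))) {
    stop("log must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(log)
  out <- out[order(out$timestamp), , drop = FALSE]  # stable sort
  pair <- paste0(out$user, "\r", out$label_id)
  within <- stats::ave(seq_along(pair), pair, FUN = seq_along)
  start <- rep(1L, nrow(out))
  if (!is.null(initial)) {
    stopifnot(all(c("user", "label_id", "start") %in% names(initial)))
    key <- paste0(initial$user, "\r", initial$label_id)
    idx <- match(pair, key)
    start[!is.na(idx)] <- as.integer(initial$start[idx[!is.na(idx)]])
  }
  bad <- which(is.na(out$query) | !nzchar(as.character(out$query)))
  if (length(bad) > 0) {
    stop("empty query at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         " of the time-sorted log", call. = FALSE)
  }
  out$qlen <- qlen(out$query)
  out$seniority <- start + within - 1L
  out
}

#' Annotate suggestion ranks
#'
#' Recomputes, for every record, the position (Rank) at which the selected
#' label appeared in the completion list for the typed query — the
#' distinctiveness objective. Records whose query does not surface the
#' selected label within the top `J` are kept and flagged infeasible
#' (`rank` is `NA`), never silently dropped; their count is attached as the
#' attribute `"infeasible"` and reported with a message.
#'
#' Logs exported from a live system may already carry the historical rank;
#' set `use_recorded = TRUE` to keep an existing `rank` column instead of
#' recomputing (synthetic logs always recompute).
#'
#' @param log A data frame with columns `query` and `label_id`.
#' @param trm The [terminology()] covering every `label_id` in the log.
#' @param J Suggestion-list cap.
#' @param use_recorded Keep a pre-existing `rank` column as-is.
#' @return The log with integer `rank` and logical `feasible` columns.
#' @export
annotate_rank <- function(log, trm, J = 30L, use_recorded = FALSE) {
  stopifnot(is.data.frame(log), inherits(trm, "ppd_terminology"))
  out <- tibble::as_tibble(log)
  unknown <- setdiff(unique(out$label_id), trm$labels$label_id)
  if (length(unknown) > 0) {
    stop("log contains label_ids absent from the terminology: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (use_recorded && "rank" %in% names(out)) {
    out$rank <- as.integer(out$rank)
  } else {
    qn <- normalize_text(out$query, trm$alphabet)
    tab <- completion_table(trm, unique(qn), J)
    out$rank <- tab$rank[match(paste0(qn, "\r", out$label_id),
                               paste0(tab$query, "\r", tab$label_id))]
  }
  out$feasible <- !is.na(out$rank)
  n_bad <- sum(!out$feasible)
  attr(out, "infeasible") <- n_bad
  if (n_bad > 0) {
    message(n_bad, " record(s) infeasible: selected label not in top ",
            J, " for the recorded query")
  }
  out
}

#' Enrich a raw interaction log
#'
#' One-call wrapper adding the three derived features — query length,
#' user-label seniority and suggestion rank — to a raw log with columns
#' `user`, `query`, `label_id`, `timestamp`.
#'
#' @inheritParams assign_seniority
#' @inheritParams annotate_rank
#' @return Enriched tibble with columns `user`, `query`, `label_id`,
#'   `timestamp`, `qlen`, `seniority`, `rank`, `feasible`.
#' @export
enrich_log <- function(log, trm, J = 30L, initial = NULL, use_recorded = FALSE) {
  annotate_rank(assign_seniority(log, initial), trm, J, use_recorded)
}

#' Read or write an interaction log
#'
#' Raw logs are CSV (or JSON-lines) files with columns
#' `user,query,label_id,timestamp`; enriched logs append
#' `qlen,seniority,rank,feasible` in that order.
#'
#' @param path File ending in `.csv` or `.jsonl`.
#' @return For `read_log`, a tibble.
#' @export
read_log <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    out <- jsonlite::stream_in(file(path), verbose = FALSE)
    tibble::as_tibble(out)
  } else {
    readr::read_csv(path, col_types = readr::cols(
      user = readr::col_character(),
      query = readr::col_character(),
      label_id = readr::col_integer(),
      timestamp = readr::col_double()
    ))
  }
}

#' @rdname read_log
#' @param log Data frame to write.
#' @export
write_log <- function(log, path) {
  cols <- intersect(
    c("user", "query", "label_id", "timestamp",
      "qlen", "seniority", "rank", "feasible", "distance"),
    names(log)
  )
  readr::write_csv(log[, cols], path)
  invisible(path)
}
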