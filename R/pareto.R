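#' Empirical query space
#'
#' The set of distinct normalised queries observed at least once in a log.
#' The optimum for each label is searched inside this empirical space, not
#' in the full string space: optimising over all strings is both
#' computationally infeasible and practically meaningless, since globally
#' optimal strings tend to exploit internal identifiers users never see.
#' Queries are compared after normalisation, so case and accent variants
#' collapse to one element.
#'
#' @param log Data frame with a `query` column.
#' @param alph The [alphabet()] used for normalisation.
#' @return Character vector of distinct normalised queries (empty strings
#'   removed), sorted.
#' @export
empirical_query_space <- function(log, alph = alphabet()) {
  q <- unique(normalize_text(log$query, alph))
  sort(q[nzchar(q)])
}

#' Feasible query points for a target label
#'
#' For a target label `t`, every query of the empirical space through which
#' `t` can be selected (i.e. `t` appears in the completion list within the
#' top `J`) becomes a point with two objective values: `k`, the query
#' length in characters, and `j`, the rank of `t` in the suggestions. Both
#' are minimised: short queries are concise, low ranks are distinctive.
#'
#' @param space Character vector of normalised queries (see
#'   [empirical_query_space()]).
#' @param label_id The target label id.
#' @param trm The [terminology()].
#' @param J Suggestion-list cap.
#' @return Tibble with columns `query`, `k`, `j` (possibly zero rows).
#' @export
feasible_points <- function(space, label_id, trm, J = 30L) {
  stopifnot(inherits(trm, "ppd_terminology"))
  if (!label_id %in% trm$labels$label_id) {
    stop("unknown label_id: ", label_id, call. = FALSE)
  }
  tab <- completion_table(trm, space, J)
  tab <- tab[tab$label_id == as.integer(label_id), , drop = FALSE]
  tibble::tibble(query = tab$query, k = nchar(tab$query), j = tab$rank)
}

#' Pareto front of a two-objective point set
#'
#' Returns the non-dominated subset of a set of `(k, j)` points under
#' simultaneous minimisation: point a dominates point b when `a.k <= b.k`
#' and `a.j <= b.j` with at least one inequality strict. Duplicated
#' `(k, j)` pairs keep a single representative, the lexicographically
#' smallest query. The result is sorted by `k` ascending, along which `j`
#' is strictly decreasing.
#'
#' @param points Tibble with columns `k`, `j` and optionally `query`.
#' @return Tibble of the non-dominated points, sorted by `k`.
#' @examples
#' pareto_front(data.frame(k = c(3, 5, 4, 6), j = c(5, 2, 7, 1)))
#' @export
pareto_front <- function(points) {
  stopifnot(is.data.frame(points))
  if (nrow(points) == 0) stop("points must be non-empty", call. = FALSE)
  pts <- tibble::as_tibble(points)
  if (!"query" %in% names(pts)) pts$query <- ""
  ord <- order(pts$k, pts$j, pts$query)
  pts <- pts[ord, , drop = FALSE]
  pts <- pts[!duplicated(pts$k), , drop = FALSE]       # min j (and query) per k
  # a row survives iff its j beats every j at strictly smaller k
  prev_min <- c(Inf, cummin(pts$j)[-nrow(pts)])
  pts[pts$j < prev_min, , drop = FALSE]
}

#' Extreme optima of a feasible point set
#'
#' The two ends of the trade-off: the shortest feasible query (minimal `k`,
#' ties broken by minimal `j` then lexicographic query) and the
#' best-ranked query (minimal `j`, ties by minimal `k` then query). Both
#' are always members of the Pareto front.
#'
#' @inheritParams pareto_front
#' @return A list with elements `shortest` and `best_rank`, each a one-row
#'   tibble.
#' @export
extreme_optima <- function(points) {
  stopifnot(is.data.frame(points))
  if (nrow(points) == 0) stop("points must be non-empty", call. = FALSE)
  pts <- tibble::as_tibble(points)
  if (!"query" %in% names(pts)) pts$query <- ""
  o1 <- order(pts$k, pts$j, pts$query)[1]
  o2 <- order(pts$j, pts$k, pts$query)[1]
  list(shortest = pts[o1, , drop = FALSE], best_rank = pts[o2, , drop = FALSE])
}

#' Euclidean distance to the nearest Pareto-front point
#'
#' The convergence metric: the distance from an interaction's `(k, j)`
#' point to its nearest Pareto-optimal counterpart, in raw units
#' (characters on one axis, rank positions on the other). An optional
#' min-max normalised variant rescales both axes to the front's bounding
#' box before measuring, for sensitivity analyses.
#'
#' @param k,j Numeric vectors (recycled to common length) giving the query
#'   length and rank of each interaction.
#' @param front A [pareto_front()] (non-empty tibble with `k`, `j`).
#' @param normalize Use min-max normalised axes (default `FALSE`: raw units).
#' @return Numeric vector of distances, zero exactly for points that
#'   coincide with a front member.
#' @examples
#' distance_to_front(5, 4, data.frame(k = c(3, 4), j = c(1, 2)))
#' @export
distance_to_front <- function(k, j, front, normalize = FALSE) {
  stopifnot(is.data.frame(front))
  if (nrow(front) == 0) stop("front must be non-empty", call. = FALSE)
  n <- max(length(k), length(j))
  k <- rep_len(as.numeric(k), n)
  j <- rep_len(as.numeric(j), n)
  fk <- as.numeric(front$k)
  fj <- as.numeric(front$j)
  if (normalize) {
    rk <- max(diff(range(fk)), 1)
    rj <- max(diff(range(fj)), 1)
    k <- k / rk; fk <- fk / rk
    j <- j / rj; fj <- fj / rj
  }
  d2 <- outer(k, fk, "-")^2 + outer(j, fj, "-")^2
  sqrt(apply(d2, 1, min))
}

#' Pareto fronts for every label of a log
#'
#' Computes, in one pass, the per-label Pareto front over the empirical
#' query space of the log. By default the space is global — any query
#' observed anywhere in the log counts as feasible for a label when the
#' label appears in its completions — which matches the definition of the
#' empirical optimum. `scope = "per_label"` restricts each label's space to
#' the queries used when that label was actually selected, for sensitivity
#' analyses.
#'
#' @param log Data frame with `query` and `label_id` columns.
#' @param trm The [terminology()].
#' @param J Suggestion-list cap.
#' @param scope `"global"` (default) or `"per_label"`.
#' @return Tibble with columns `label_id`, `query`, `k`, `j`: the front
#'   rows of every label that has at least one feasible query.
#' @export
pareto_fronts <- function(log, trm, J = 30L, scope = c("global", "per_label")) {
  scope <- match.arg(scope)
  stopifnot(inherits(trm, "ppd_terminology"))
  space <- empirical_query_space(log, trm$alphabet)
  tab <- completion_table(trm, space, J)
  tab <- tab[tab$label_id %in% unique(as.integer(log$label_id)), , drop = FALSE]
  if (scope == "per_label") {
    used <- unique(paste0(normalize_text(log$query, trm$alphabet), "\r", log$label_id))
    tab <- tab[paste0(tab$query, "\r", tab$label_id) %in% used, , drop = FALSE]
  }
  tab$k <- nchar(tab$query)
  parts <- split(tab, tab$label_id)
  out <- lapply(parts, function(p) {
    fr <- pareto_front(tibble::tibble(query = p$query, k = p$k, j = p$rank))
    fr$label_id <- p$label_id[1]
    fr
  })
  res <- dplyr::bind_rows(out)
  res[, c("label_id", "query", "k", "j")]
}

#' Append distance-to-front to an enriched log
#'
#' Looks up each record's label front and measures the Euclidean distance
#' from the record's `(qlen, rank)` point to it. Infeasible records (no
#' rank) and records of labels without a front get `NA`.
#'
#' @param log Enriched log (columns `label_id`, `qlen`, `rank`).
#' @param fronts Output of [pareto_fronts()].
#' @param normalize Passed to [distance_to_front()].
#' @return The log with a `distance` column appended.
#' @export
annotate_distance <- function(log, fronts, normalize = FALSE) {
  stopifnot(is.data.frame(log), is.data.frame(fronts))
  out <- tibble::as_tibble(log)
  out$distance <- NA_real_
  for (lid in unique(out$label_id)) {
    fr <- fronts[fronts$label_id == lid, , drop = FALSE]
    sel <- which(out$label_id == lid & !is.na(out$rank))
    if (nrow(fr) > 0 && length(sel) > 0) {
      out$distance[sel] <- distance_to_front(out$qlen[sel], out$rank[sel],
                                             fr, normalize)
    }
  }
  out
}

#' Write per-label Pareto fronts to CSV
#'
#' @param fronts Output of [pareto_fronts()].
#' @param path Output CSV path (columns `label_id,query,k,j`).
#' @export
write_fronts <- function(fronts, path) {
  readr::write_csv(fronts, path)
  invisible(path)
}
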