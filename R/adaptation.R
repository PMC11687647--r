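#' Keep labels used consistently up to a seniority cap
#'
#' Label popularity is heavy-tailed, so the set of labels present at each
#' seniority level drifts: rarely chosen labels never reach high levels.
#' To compare like with like across the seniority axis, this filter keeps
#' only records of labels that are attained at level `S_max` by at least
#' one (user, label) pair, and drops the rest (counts are attached as the
#' attribute `"removed"`).
#'
#' @param log Enriched log (columns `label_id`, `seniority`).
#' @param S_max Target seniority level; must not exceed the maximum
#'   observed seniority.
#' @return Filtered log; `attr(, "removed")` holds the dropped record and
#'   label counts.
#' @export
consistency_filter <- function(log, S_max) {
  stopifnot(is.data.frame(log), "seniority" %in% names(log))
  if (S_max > max(log$seniority)) {
    stop("S_max (", S_max, ") exceeds the maximum observed seniority (",
         max(log$seniority), ")", call. = FALSE)
  }
  keep_labels <- unique(log$label_id[log$seniority >= S_max])
  out <- log[log$label_id %in% keep_labels, , drop = FALSE]
  attr(out, "removed") <- c(
    records = nrow(log) - nrow(out),
    labels = length(unique(log$label_id)) - length(keep_labels)
  )
  out
}

#' Representativeness of high-seniority samples
#'
#' At each seniority level only a subset of the (user, label) pairs is
#' still observed; analyses along the seniority axis are trustworthy only
#' up to the level where that subset stays representative of the full pair
#' population. The margin of error of a proportion estimated from `n` of
#' `N` pairs, at the conservative p = 0.5 and with finite-population
#' correction, is
#' `e = z * sqrt(0.25 / n) * sqrt((N - n) / (N - 1))`,
#' where `N` is the number of pairs at level 1 and `z` the normal quantile
#' of the requested confidence. The recommended cap `s_max` is the largest
#' level such that `e <= margin` holds at it and at every level below.
#'
#' @param log Enriched log (columns `user`, `label_id`, `seniority`).
#' @param margin Tolerated margin of error, in (0, 1) (default 0.03).
#' @param confidence Confidence level in (0, 1) (default 0.95).
#' @return A list of class `ppd_repr_report`: `$levels` (tibble with
#'   `level`, `n`, `margin_of_error`), `$s_max`, `$N`, `$z`, `$margin`,
#'   `$confidence`.
#' @export
representative_cap <- function(log, margin = 0.03, confidence = 0.95) {
  stopifnot(is.data.frame(log), nrow(log) > 0)
  stopifnot(margin > 0, margin < 1, confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  pair <- paste0(log$user, "\r", log$label_id)
  top <- tapply(log$seniority, pair, max)
  N <- length(top)
  levels <- seq_len(max(log$seniority))
  n <- vapply(levels, function(l) sum(top >= l), numeric(1))
  e <- z * sqrt(0.25 / n) * sqrt(pmax(N - n, 0) / max(N - 1, 1))
  ok <- cumprod(e <= margin) == 1
  structure(list(
    levels = tibble::tibble(level = levels, n = as.integer(n),
                            margin_of_error = e),
    s_max = if (any(ok)) max(levels[ok]) else 0L,
    N = N, z = z, margin = margin, confidence = confidence
  ), class = "ppd_repr_report")
}

#' @export
print.ppd_repr_report <- function(x, ...) {
  cat("<representativeness report> N =", x$N, "pairs; margin <=", x$margin,
      "at confidence", x$confidence, "holds up to seniority", x$s_max, "\n")
  invisible(x)
}

#' Mean and spread of a tracked quantity by seniority level
#'
#' Aggregates an enriched log along the user-label seniority axis: at each
#' level, the number of records and the arithmetic mean and population
#' standard deviation of the chosen quantity over all records at that
#' level. Levels with no records are simply absent from the result (a gap),
#' never interpolated. Records with a missing value (e.g. infeasible rank)
#' are excluded from that level's aggregate.
#'
#' @param log Enriched log.
#' @param metric One of `"distance"`, `"qlen"`, `"rank"`, or the name of
#'   any numeric column of `log`.
#' @param S_max Optional cap: levels above it are dropped.
#' @return Tibble of class `ppd_seniority_curve` with columns `level`, `n`,
#'   `mean`, `std`.
#' @export
curve_by_seniority <- function(log, metric = c("distance", "qlen", "rank"),
                               S_max = NULL) {
  metric <- if (is.character(metric)) metric[1] else stop("metric must be a name")
  stopifnot(is.data.frame(log), "seniority" %in% names(log))
  if (!metric %in% names(log)) {
    stop("log has no column '", metric, "'; enrich/annotate it first",
         call. = FALSE)
  }
  x <- as.numeric(log[[metric]])
  lev <- log$seniority
  keep <- !is.na(x)
  if (!is.null(S_max)) keep <- keep & lev <= S_max
  x <- x[keep]; lev <- lev[keep]
  if (length(x) == 0) stop("no usable records for metric '", metric, "'", call. = FALSE)
  n <- tapply(x, lev, length)
  m <- tapply(x, lev, mean)
  v <- tapply(x, lev, function(z) mean((z - mean(z))^2))  # population variance
  out <- tibble::tibble(
    level = as.integer(names(n)), n = as.integer(n),
    mean = as.numeric(m), std = sqrt(as.numeric(v))
  )
  out <- out[order(out$level), , drop = FALSE]
  class(out) <- c("ppd_seniority_curve", class(out))
  attr(out, "metric") <- metric
  out
}

#' Savitzky-Golay smoothing of a numeric series
#'
#' Each point is replaced by the value, at its own position, of a
#' degree-`polyorder` polynomial least-squares fit over the window centred
#' on it. Near the series ends the window is truncated to the available
#' points, which keeps the fit local instead of reusing the first full
#' window off-centre. Polynomials of degree up to `polyorder` are
#' reproduced exactly.
#'
#' @param x Numeric vector.
#' @param window Odd window width, at most `length(x)`.
#' @param polyorder Polynomial degree, strictly less than `window`.
#' @return Numeric vector of the same length.
#' @examples
#' sgolay_smooth(c(1, 4, 9, 16, 25, 36, 49) / 7, window = 5, polyorder = 2)
#' @export
sgolay_smooth <- function(x, window = 11L, polyorder = 2L) {
  n <- length(x)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")",
                       call. = FALSE)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - h):min(n, i + h)
    t <- idx - i
    deg <- min(polyorder, length(idx) - 1L)
    fit <- stats::lm.fit(outer(t, 0:deg, "^"), x[idx])
    out[i] <- fit$coefficients[1]  # polynomial evaluated at t = 0
  }
  out
}

#' Savitzky-Golay smoothing of a seniority curve
#'
#' Appends a `mean_smoothed` column: the mean sequence filtered by a
#' sliding polynomial least-squares fit. Savitzky-Golay filtering
#' reproduces polynomial trends up to its order exactly while averaging
#' out level-to-level noise, which makes it a conservative choice for
#' visualising adaptation trends. Near the curve ends the window is
#' truncated to the available levels.
#'
#' @param curve A [curve_by_seniority()] result (or any data frame with a
#'   `mean` column).
#' @param window Odd window width, at most the number of levels
#'   (default 11).
#' @param polyorder Polynomial degree, strictly less than `window`
#'   (default 2).
#' @return The curve with a `mean_smoothed` column.
#' @export
smooth_curve <- function(curve, window = 11L, polyorder = 2L) {
  stopifnot(is.data.frame(curve), "mean" %in% names(curve))
  curve$mean_smoothed <- sgolay_smooth(curve$mean, window, polyorder)
  curve
}

#' Bootstrap confidence interval for the seniority trend
#'
#' Fits a straight line to the per-level means of a tracked quantity and
#' bootstraps its slope by resampling (user, label) pairs with
#' replacement — the pair, not the record, is the independent unit. Used
#' as a null check: when agents never adapt, the interval should cover
#' zero, guarding against pipeline-induced artefactual trends.
#'
#' By default the fit is balanced at the pair level: only pairs that
#' attain `S_max` enter, so every level aggregates the same pairs. Pooling
#' all records instead (`balanced = FALSE`) mixes a different pair
#' population into every level, and under heavy-tailed label popularity
#' that composition drift alone manufactures a trend: persistent pairs
#' belong to popular labels, whose empirical fronts are the best of many
#' draws and therefore sit farther from the average interaction. A trend
#' instrument meant to detect within-user adaptation must compare like
#' with like, which is what the balanced panel does.
#'
#' @param log Enriched log with the metric column filled.
#' @param metric Column to track (default `"distance"`).
#' @param S_max Seniority cap; required when `balanced = TRUE`.
#' @param B Number of bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param balanced Restrict to pairs attaining `S_max` (default `TRUE`).
#' @return List with `slope` (point estimate), `lower`, `upper`, `B`,
#'   `n_pairs`.
#' @export
trend_bootstrap_ci <- function(log, metric = "distance", S_max = NULL,
                               B = 200L, conf = 0.95, balanced = TRUE) {
  stopifnot(is.data.frame(log), metric %in% names(log))
  x <- as.numeric(log[[metric]])
  lev <- as.integer(log$seniority)
  pair_all <- paste0(log$user, "\r", log$label_id)
  keep <- !is.na(x)
  if (!is.null(S_max)) keep <- keep & lev <= S_max
  if (balanced) {
    if (is.null(S_max)) stop("balanced = TRUE needs S_max", call. = FALSE)
    top <- tapply(lev, pair_all, max)
    keep <- keep & pair_all %in% names(top)[top >= S_max]
  }
  x <- x[keep]; lev <- lev[keep]
  pair <- pair_all[keep]
  pid <- match(pair, unique(pair))
  n_pairs <- max(pid)
  lev_f <- factor(lev)
  lev_num <- as.numeric(levels(lev_f))

  slope_of <- function(w) {
    ww <- w[pid]
    s <- rowsum(ww * x, lev_f)
    cnt <- rowsum(ww, lev_f)
    ok <- cnt > 0
    m <- s[ok] / cnt[ok]
    l <- lev_num[ok]
    if (length(m) < 3) return(NA_real_)
    stats::cov(l, m) / stats::var(l)
  }
  slope <- slope_of(rep(1, n_pairs))
  boots <- vapply(seq_len(B), function(b) {
    slope_of(tabulate(sample.int(n_pairs, n_pairs, replace = TRUE), n_pairs))
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(slope = slope, lower = qs[1], upper = qs[2], B = B, n_pairs = n_pairs)
}

#' Write a seniority curve to CSV
#'
#' @param curve A curve, optionally smoothed.
#' @param path Output path (columns `level,n,mean,std[,mean_smoothed]`).
#' @export
write_curve <- function(curve, path) {
  readr::write_csv(as.data.frame(curve), path)
  invisible(path)
}
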