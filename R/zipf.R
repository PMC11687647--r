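#' Tokenise text into words
#'
#' Normalises and splits on spaces, dropping empties. Used to build
#' word-level rank-frequency distributions from queries or label texts.
#'
#' @param text Character vector.
#' @param alph The [alphabet()].
#' @return Character vector of tokens (all inputs concatenated).
#' @examples
#' tokenize("Diabète de type 2")
#' @export
tokenize <- function(text, alph = alphabet()) {
  toks <- unlist(strsplit(normalize_text(text, alph), " ", fixed = TRUE),
                 use.names = FALSE)
  toks[nzchar(toks)]
}

#' Rank-frequency table
#'
#' Counts distinct items and assigns ranks 1..n by decreasing frequency,
#' ties broken lexicographically (tied frequencies receive distinct
#' consecutive ranks). Rank 1 is the most frequent item.
#'
#' @param tokens Non-empty character vector of items (words, queries or
#'   label ids as strings).
#' @return Tibble with columns `item`, `frequency`, `rank`.
#' @examples
#' rank_frequency(c("a", "b", "a"))
#' @export
rank_frequency <- function(tokens) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0) stop("tokens must be non-empty", call. = FALSE)
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab))
  tibble::tibble(
    item = names(tab)[ord],
    frequency = as.integer(tab)[ord],
    rank = seq_along(tab)
  )
}

#' Power-law fit of a rank-frequency table
#'
#' Ordinary least squares on (log10 rank, log10 frequency) within a rank
#' window. For a Zipfian distribution `f(r) = C * r^(-s)` the fitted slope
#' is `-s`. The window exists to exclude the low-frequency tail, where
#' discreteness (many frequency-1 items) flattens the log-log plot.
#'
#' @param table A [rank_frequency()] table.
#' @param min_rank,max_rank Inclusive fit range (default: all ranks).
#' @return List with `slope`, `intercept`, `r_squared`, `n_points` and the
#'   fit range.
#' @examples
#' tab <- rank_frequency(rep(letters[1:4], c(40, 20, 13, 10)))
#' powerlaw_fit(tab)$slope
#' @export
powerlaw_fit <- function(table, min_rank = 1L, max_rank = Inf) {
  stopifnot(is.data.frame(table),
            all(c("rank", "frequency") %in% names(table)))
  sub <- table[table$rank >= min_rank & table$rank <= max_rank, , drop = FALSE]
  if (nrow(sub) < 3) {
    stop("need at least 3 ranks in the fit range", call. = FALSE)
  }
  lx <- log10(sub$rank)
  ly <- log10(sub$frequency)
  fit <- stats::lm(ly ~ lx)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n_points = nrow(sub),
    min_rank = min_rank, max_rank = max_rank
  )
}
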