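#' Build a terminology
#'
#' A terminology is the closed list of selectable labels (a clinical problem
#' list, for instance), each with a canonical text and optional synonyms.
#' The constructor normalises every text variant once and builds the word
#' index used by the completion engine, so lookups against a fixed
#' terminology are cheap.
#'
#' @param labels A data frame with columns `label_id` (unique positive
#'   integers), `canonical_text` (non-empty strings) and optionally
#'   `synonyms` (either a list-column of character vectors or a
#'   pipe-separated string column).
#' @param alph The [alphabet()] used for normalisation.
#' @return An object of class `ppd_terminology`. Fields of interest:
#'   `$labels` (tibble of id, canonical text and synonyms), `$L` (length of
#'   the longest normalised canonical text).
#' @examples
#' trm <- terminology(data.frame(
#'   label_id = c(2477, 4578),
#'   canonical_text = c("Accident vasculaire cérébral ischémique",
#'                      "Diabète de Type 2"),
#'   synonyms = c("avc", "")
#' ))
#' trm$L
#' @export
terminology <- function(labels, alph = alphabet()) {
  stopifnot(is.data.frame(labels))
  if (!all(c("label_id", "canonical_text") %in% names(labels))) {
    stop("labels must have columns label_id and canonical_text", call. = FALSE)
  }
  if (nrow(labels) < 1L) stop("terminology needs at least one label", call. = FALSE)
  ids <- as.integer(labels$label_id)
  if (anyNA(ids) || any(ids < 1L)) {
    stop("label_id must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("label_id values must be unique", call. = FALSE)

  syn <- if ("synonyms" %in% names(labels)) labels$synonyms else rep("", nrow(labels))
  if (!is.list(syn)) {
    syn <- strsplit(ifelse(is.na(syn), "", as.character(syn)), "|", fixed = TRUE)
  }
  syn <- lapply(syn, function(s) s[nzchar(s)])

  canon_norm <- normalize_text(labels$canonical_text, alph)
  if (any(!nzchar(canon_norm))) {
    stop("canonical_text must be non-empty after normalization", call. = FALSE)
  }

  lab_tbl <- tibble::tibble(
    label_id = ids,
    canonical_text = as.character(labels$canonical_text),
    canonical_norm = canon_norm,
    synonyms = syn
  )

  # one "entry" per normalised text variant (canonical or synonym)
  n_syn <- lengths(syn)
  entry_label <- c(seq_len(nrow(lab_tbl)), rep(seq_len(nrow(lab_tbl)), n_syn))
  entry_text <- c(canon_norm, normalize_text(unlist(syn, use.names = FALSE), alph))
  keep <- nzchar(entry_text)
  entry_label <- entry_label[keep]
  entry_text <- entry_text[keep]

  words <- strsplit(entry_text, " ", fixed = TRUE)
  obj <- list(
    labels = lab_tbl,
    alphabet = alph,
    L = max(nchar(canon_norm)),
    entry_text = entry_text,
    entry_label = entry_label,           # row index into $labels
    entry_nchar = nchar(entry_text),
    word = unlist(words, use.names = FALSE),
    word_entry = rep(seq_along(entry_text), lengths(words)),
    cache = new.env(parent = emptyenv())
  )
  class(obj) <- "ppd_terminology"
  obj
}

#' @export
print.ppd_terminology <- function(x, ...) {
  cat("<terminology> ", nrow(x$labels), " labels, ",
      length(x$entry_text), " text variants, L = ", x$L, "\n", sep = "")
  invisible(x)
}

#' Read or write a terminology file
#'
#' Two on-disk formats are supported: a UTF-8 CSV with columns
#' `label_id,canonical_text,synonyms` (synonyms pipe-separated, empty
#' allowed) and a JSON array of objects `{id, text, synonyms}`. The format
#' is chosen by file extension.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param alph The [alphabet()] used for normalisation.
#' @return For `read_terminology`, a `ppd_terminology`.
#' @export
read_terminology <- function(path, alph = alphabet()) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- data.frame(
      label_id = vapply(raw, function(x) as.integer(x$id), integer(1)),
      canonical_text = vapply(raw, function(x) as.character(x$text), character(1))
    )
    df$synonyms <- lapply(raw, function(x) as.character(unlist(x$synonyms)))
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(
      label_id = readr::col_integer(),
      canonical_text = readr::col_character(),
      synonyms = readr::col_character()
    ))
  }
  terminology(df, alph)
}

#' @rdname read_terminology
#' @param trm A `ppd_terminology` to serialise.
#' @export
write_terminology <- function(trm, path) {
  stopifnot(inherits(trm, "ppd_terminology"))
  df <- tibble::tibble(
    label_id = trm$labels$label_id,
    canonical_text = trm$labels$canonical_text,
    synonyms = vapply(trm$labels$synonyms, paste, character(1), collapse = "|")
  )
  readr::write_csv(df, path)
  invisible(path)
}
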