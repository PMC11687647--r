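#' Query alphabet
#'
#' The closed symbol set over which queries live. The completion engine and
#' the string-space combinatorics both operate on this alphabet; characters
#' outside it are removed by [normalize_text()]. The default alphabet has 37
#' symbols: the lowercase letters `a`-`z`, the digits `0`-`9`, and the space
#' character.
#'
#' @param symbols Character vector of single characters. Must be non-empty,
#'   free of duplicates, and contain the space character (queries are
#'   tokenised on spaces).
#' @return An object of class `ppd_alphabet`: a character vector of symbols
#'   with the regular-expression character class used for filtering attached.
#' @examples
#' alphabet()
#' length(alphabet())
#' @export
alphabet <- function(symbols = c(letters, as.character(0:9), " ")) {
  if (length(symbols) == 0) {
    stop("alphabet must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be unique", call. = FALSE)
  }
  if (any(nchar(symbols) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (!" " %in% symbols) {
    stop("alphabet must contain the space character", call. = FALSE)
  }
  cls <- paste0(
    "[^",
    gsub("([][\\^-])", "\\\\\\1", paste(symbols, collapse = "")),
    "]"
  )
  structure(symbols, class = "ppd_alphabet", drop_regex = cls)
}

#' @export
print.ppd_alphabet <- function(x, ...) {
  cat("<alphabet> ", length(x), " symbols: ",
      paste(unclass(x), collapse = ""), "\n", sep = "")
  invisible(x)
}

# Latin-1 / French accent repertoire; folding is an explicit table so the
# result does not depend on the session locale or on iconv's platform quirks.
.accented <- paste0(
  "àáâãäåçèéêë",
  "ìíîïñòóôõöù",
  "úûüýÿ",
  "ÀÁÂÃÄÅÇÈÉÊË",
  "ÌÍÎÏÑÒÓÔÕÖÙ",
  "ÚÛÜÝ"
)
.unaccented <- paste0(
  "aaaaaaceeee", "iiiinooooou", "uuuyy",
  "AAAAAACEEEE", "IIIINOOOOOU", "UUUY"
)

#' Normalise free text into the query alphabet
#'
#' Lowercases, folds accented Latin characters to their base character
#' (é to e, ç to c, ...), drops every character outside the alphabet,
#' collapses whitespace runs to single spaces and strips leading/trailing
#' spaces. Terminology labels are written in accented French while queries
#' are typed in the plain alphabet, so both sides of every comparison in the
#' package go through this function first. The empty string is a legal
#' output.
#'
#' @param text Character vector to normalise.
#' @param alph An [alphabet()].
#' @return Character vector of the same length.
#' @examples
#' normalize_text("Diabète de Type 2")
#' normalize_text("Hypertension   Artérielle!")
#' @export
normalize_text <- function(text, alph = alphabet()) {
  stopifnot(inherits(alph, "ppd_alphabet"))
  out <- chartr(.accented, .unaccented, as.character(text))
  out <- tolower(out)
  out <- gsub(attr(alph, "drop_regex"), "", out, perl = TRUE)
  out <- gsub(" +", " ", out)
  trimws(out)
}

#' Size of the bounded string space
#'
#' Number of non-empty strings of length at most `L` over an alphabet of
#' `n_symbols` characters: the geometric sum over lengths 1..L, whose closed
#' form is (n^(L+1) - n) / (n - 1). This is the size of the full solution
#' space that the empirical query space is a subset of.
#'
#' @param n_symbols Alphabet size (a positive integer), or an [alphabet()].
#' @param L Maximum string length, at least 1.
#' @return The count, as a double (the count overflows integer storage
#'   already for a 37-symbol alphabet at L = 7).
#' @examples
#' string_space_size(38, 2) # 38 + 38^2 = 1482
#' string_space_size(alphabet(), 1)
#' @export
string_space_size <- function(n_symbols, L) {
  if (inherits(n_symbols, "ppd_alphabet")) n_symbols <- length(n_symbols)
  n <- as.numeric(n_symbols)
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("n_symbols must be a positive integer", call. = FALSE)
  }
  if (length(L) != 1L || is.na(L) || L < 1) {
    stop("L must be a positive integer (L >= 1)", call. = FALSE)
  }
  L <- floor(L)
  if (n == 1) return(L)
  (n^(L + 1) - n) / (n - 1)
}
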