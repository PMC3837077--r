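# Small closed word lists used by the orthographic and content-word features.
# Kept in code (not external resources): generic English function words and
# Greek letter names, nothing domain specific.
.stop_words <- c(
  "a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "from",
  "has", "have", "in", "is", "it", "its", "of", "on", "or", "that", "the",
  "to", "was", "were", "which", "with", "this", "these", "those", "not",
  "no", "we", "our", "their", "they", "been", "than", "then", "there", "also")

.greek_letters <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
  "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
  "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega")

#' Word-shape normalization
#'
#' Maps a token to its orthographic equivalence class: every capital letter
#' becomes `A`, every lowercase letter becomes `a`, every maximal run of
#' digits becomes a single `0`, and all other characters are preserved.
#' `IL` -> `AA`, `IL-2` -> `AA-0`, `IL-88` -> `AA-0`.
#'
#' @param surface character vector of non-empty token surfaces.
#' @return character vector of shapes.
#' @export
word_shape <- function(surface) {
  if (any(!nzchar(surface))) stop("empty surface form")
  x <- gsub("[A-Z]", "A", surface)
  x <- gsub("[a-z]", "a", x)
  gsub("[0-9]+", "0", x)
}

#' Word-class normalization
#'
#' Coarser variant of [word_shape()] used to group similar entity names:
#' capitals -> `A`, lowercase -> `a`, digits -> `O`, any other character ->
#' `-`, then consecutive identical characters are squeezed to one.
#' `IL23R` -> `AOA`, `mRNA` -> `aA`.
#'
#' @param surface character vector of non-empty token surfaces.
#' @return character vector of word classes.
#' @export
word_class <- function(surface) {
  if (any(!nzchar(surface))) stop("empty surface form")
  x <- gsub("[A-Z]", "A", surface)
  x <- gsub("[a-z]", "a", x)
  x <- gsub("[0-9]", "O", x)
  x <- gsub("[^AaO]", "-", x)
  gsub("(.)\\1+", "\\1", x)
}

# Crude stemmer backing the "normalization" feature: lower-case, strip plural
# s/es and the inflections ing/ed, collapse digit runs.  Approximate by
# design; the feature only needs a stable equivalence class.
word_stem <- function(surface) {
  x <- tolower(surface)
  x <- sub("(ing|ed)$", "", x)
  x <- sub("(es|s)$", "", x)
  gsub("[0-9]+", "0", x)
}

.ortho_names <- c(
  "InitCap", "AllCaps", "InCap", "CapMixAlpha", "DigitOnly", "DigitSpecial",
  "DigitAlpha", "AlphaDigitAlpha", "Hyphen", "CapLowAlpha", "CapsAndDigits",
  "RomanNumeral", "StopWord", "ATGCSeq", "AlphaDigit", "DigitCommaDigit",
  "GreekLetter", "LowMixAlpha")

#' Orthographic feature flags
#'
#' Binary indicators over the standard orthographic categories used for
#' biomedical entity tokens (capitalization and digit patterns, hyphens,
#' Roman numerals, nucleotide-sequence-like strings, stop words, Greek letter
#' names).  Categories are not mutually exclusive.
#'
#' @param surface a single non-empty token surface.
#' @return named integer (0/1) vector over the categories.
#' @export
orthographic_flags <- function(surface) {
  stopifnot(length(surface) == 1L, nzchar(surface))
  s <- surface
  has_upper <- grepl("[A-Z]", s)
  has_lower <- grepl("[a-z]", s)
  has_digit <- grepl("[0-9]", s)
  all_alpha <- grepl("^[A-Za-z]+$", s)
  flags <- c(
    InitCap         = grepl("^[A-Z]", s),
    AllCaps         = grepl("^[A-Z]+$", s),
    InCap           = grepl("^.+[A-Z]", s),
    CapMixAlpha     = all_alpha && grepl("^[A-Z]", s) && has_lower && has_upper,
    DigitOnly       = grepl("^[0-9]+$", s),
    DigitSpecial    = has_digit && !has_upper && !has_lower &&
                      grepl("[^0-9]", s),
    DigitAlpha      = grepl("^[0-9]", s) && grepl("[A-Za-z]", s),
    AlphaDigitAlpha = grepl("^[A-Za-z]+[0-9]+[A-Za-z]+[A-Za-z0-9]*$", s),
    Hyphen          = grepl("-", s, fixed = TRUE),
    CapLowAlpha     = grepl("^[A-Z][a-z]+$", s),
    CapsAndDigits   = has_upper && has_digit,
    RomanNumeral    = grepl("^[IVXLCDM]+$", s),
    StopWord        = tolower(s) %in% .stop_words,
    ATGCSeq         = grepl("^[ATGCU]+$", s) && nchar(s) >= 2L,
    AlphaDigit      = grepl("^[A-Za-z]+[0-9]+$", s),
    DigitCommaDigit = grepl("^[0-9]+,[0-9]+$", s),
    GreekLetter     = tolower(s) %in% .greek_letters,
    LowMixAlpha     = all_alpha && grepl("^[a-z]", s) && has_upper
  )
  stats::setNames(as.integer(flags), .ortho_names)
}
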