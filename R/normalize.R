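#' Normalize a term or free-text string
#'
#' Applies the single normalization convention used everywhere in the package
#' (lexicons, report strings, literature sentences, gold-standard pairs), so
#' that string matching is deterministic across modules: Unicode NFC, lower
#' case, whitespace collapsed to single spaces, surrounding whitespace and
#' punctuation stripped.
#'
#' Normalization is idempotent: `pb_normalize(pb_normalize(x))` equals
#' `pb_normalize(x)`.
#'
#' @param x character vector.
#' @return character vector of the same length, normalized.
#' @examples
#' pb_normalize("  NAUSEA ")        # "nausea"
#' pb_normalize("-Warfarin  SODIUM-")  # "warfarin sodium"
#' @export
pb_normalize <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  x <- gsub("(^[[:punct:][:space:]]+)|([[:punct:][:space:]]+$)", "", x, perl = TRUE)
  x
}

# Tokenize normalized text into alphanumeric runs. Punctuation and whitespace
# are delimiters, never part of a token, so "erbitux/bms" -> c("erbitux","bms").
# Returns a list of character vectors (one per input string).
pb_tokenize <- function(x) {
  toks <- stringi::stri_extract_all_regex(x, "[[:alnum:]]+", omit_no_match = TRUE)
  lapply(toks, function(t) if (length(t) == 1L && is.na(t)) character(0) else t)
}

# Canonical single-string token form of a term: tokens joined by one space.
# Two strings match on token boundaries iff their token keys are equal.
pb_token_key <- function(x) {
  vapply(pb_tokenize(pb_normalize(x)), paste, character(1), collapse = " ")
}
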