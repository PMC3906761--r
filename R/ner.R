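# Dictionary engine shared by drug NER, side-effect NER and the literature
# index: terms are stored under their token key (normalized tokens joined by
# single spaces), and matching is greedy leftmost-longest over the token
# sequence of the input. Token boundaries are hard: a term never matches
# inside a longer word.

pb_dict_build <- function(terms, canonical = terms) {
  keys <- pb_token_key(terms)
  canonical <- pb_normalize(canonical)
  keep <- nzchar(keys)
  keys <- keys[keep]; canonical <- canonical[keep]
  # deterministic under permutation of the input: smallest canonical wins ties
  o <- order(keys, canonical)
  keys <- keys[o]; canonical <- canonical[o]
  first <- !duplicated(keys)
  env <- new.env(parent = emptyenv(), size = max(16L, length(keys)))
  ks <- keys[first]; cs <- canonical[first]
  for (i in seq_along(ks)) assign(ks[i], cs[i], envir = env)
  lens <- lengths(strsplit(ks, " ", fixed = TRUE))
  list(env = env, max_len = if (length(lens)) max(lens) else 0L)
}

# Greedy leftmost-longest match of dictionary terms over a token vector.
# Returns data.frame(canonical, tok_start, tok_end); zero rows if no match.
pb_match_tokens <- function(tokens, dict) {
  n <- length(tokens)
  out_can <- character(0); out_s <- integer(0); out_e <- integer(0)
  if (n == 0L || dict$max_len == 0L) {
    return(data.frame(canonical = out_can, tok_start = out_s, tok_end = out_e,
                      stringsAsFactors = FALSE))
  }
  i <- 1L
  while (i <= n) {
    hit <- FALSE
    for (L in seq.int(min(dict$max_len, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      val <- get0(key, envir = dict$env, inherits = FALSE)
      if (!is.null(val)) {
        out_can <- c(out_can, val); out_s <- c(out_s, i); out_e <- c(out_e, i + L - 1L)
        i <- i + L
        hit <- TRUE
        break
      }
    }
    if (!hit) i <- i + 1L
  }
  data.frame(canonical = out_can, tok_start = out_s, tok_end = out_e,
             stringsAsFactors = FALSE)
}

# drug dictionary: generics map to themselves, trade names to their generic
pb_drug_dict <- function(lex) {
  stopifnot(inherits(lex, "drug_lexicon"))
  pb_dict_build(c(lex$generics, names(lex$trade_to_generic)),
                c(lex$generics, unname(lex$trade_to_generic)))
}

# vectorized core: list of canonical-entity vectors, one per input string,
# deduplicated preserving first occurrence; caches over unique inputs
pb_ner_entities <- function(strings, dict) {
  u <- unique(strings)
  toks <- pb_tokenize(pb_normalize(u))
  res <- lapply(toks, function(t) unique(pb_match_tokens(t, dict)$canonical))
  res[match(strings, u)]
}

#' Recognize drug entities in a free-text drug string
#'
#' Dictionary-based drug named-entity recognition: greedy leftmost-longest
#' matching of lexicon names (generic and trade) on token boundaries, with
#' trade names replaced by their generic names. There is no fuzzy matching:
#' misspelled drug names yield no match. The result is deduplicated
#' preserving first occurrence, so a combination product yields each generic
#' once.
#'
#' @param s a single free-text drug string, e.g.
#'   `"erbitux 100 mg imclone /bms"`.
#' @param lex a [drug_lexicon()].
#' @return character vector of generic names (possibly empty).
#' @examples
#' lex <- drug_lexicon(c("cetuximab", "warfarin"), c(erbitux = "cetuximab"))
#' recognize_drugs("erbitux 100 mg imclone /bms", lex)  # "cetuximab"
#' recognize_drugs("wrfarin", lex)                      # character(0)
#' @export
recognize_drugs <- function(s, lex) {
  stopifnot(length(s) == 1L)
  pb_ner_entities(s, pb_drug_dict(lex))[[1]]
}

#' Recognize a side-effect entity in a coded event string
#'
#' Event strings in spontaneous reports are coded with MedDRA terminology, so
#' recognition is exact whole-string matching (after normalization) against
#' the clean side-effect lexicon: terms present in the lexicon always match,
#' terms curated out of it (medical procedures, lab tests, overly general
#' terms) never do.
#'
#' @param s a single coded event string.
#' @param lex a [se_lexicon()].
#' @return character vector with the matched term, or empty.
#' @examples
#' lex <- se_lexicon(c("nausea", "myocardial infarction"))
#' recognize_ses("NAUSEA ", lex)      # "nausea"
#' recognize_ses("abdomen scan", lex) # character(0)
#' @export
recognize_ses <- function(s, lex) {
  stopifnot(length(s) == 1L, inherits(lex, "se_lexicon"))
  key <- pb_normalize(s)
  if (key %in% lex$terms) key else character(0)
}

#' Full annotation of a drug string, with spans
#'
#' Like [recognize_drugs()] but returning the matched spans (token indices in
#' the normalized, tokenized input), useful for inspecting the matcher.
#'
#' @param s a single free-text drug string.
#' @param lex a [drug_lexicon()].
#' @return Object of class `ner_result`: list with `input_string`, `entities`
#'   (data.frame canonical/tok_start/tok_end) and `unmatched` flag.
#' @export
annotate_drugs <- function(s, lex) {
  stopifnot(length(s) == 1L)
  toks <- pb_tokenize(pb_normalize(s))[[1]]
  ents <- pb_match_tokens(toks, pb_drug_dict(lex))
  structure(list(input_string = s, entities = ents, unmatched = nrow(ents) == 0L),
            class = "ner_result")
}

#' Exact-set accuracy of entity recognition against a labeled truth
#'
#' A prediction for a string is correct iff its entity set equals the truth
#' set exactly (both empty counts as agreement). The truth must cover every
#' evaluated string.
#'
#' @param predictions named list: input string -> character vector of
#'   predicted canonical entities.
#' @param truth named list: input string -> character vector of true
#'   entities. Must have an entry for every name in `predictions`.
#' @return list with `accuracy` (fraction correct), `n` (strings evaluated),
#'   `mismatches` (character vector of strings whose sets disagree).
#' @export
ner_accuracy <- function(predictions, truth) {
  if (is.null(names(predictions)) || is.null(names(truth))) {
    pb_validation_error("predictions and truth must be named by input string")
  }
  missing <- setdiff(names(predictions), names(truth))
  if (length(missing)) {
    pb_validation_error(paste0("truth entries missing for: ",
                               paste(utils::head(missing, 5), collapse = ", ")))
  }
  ok <- vapply(names(predictions), function(s) {
    setequal(pb_normalize(predictions[[s]]), pb_normalize(truth[[s]]))
  }, logical(1))
  list(accuracy = if (length(ok)) mean(ok) else NA_real_,
       n = length(ok),
       mismatches = names(predictions)[!ok])
}
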