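#' Build an in-process literature index
#'
#' Scans every sentence of the corpus with the same dictionary matcher used
#' for report strings (case-insensitive, token-boundary, leftmost-longest;
#' trade names mapped to generics), producing postings of where each lexicon
#' term occurs. This is the local stand-in for a sentence/abstract search
#' engine over the literature.
#'
#' @param corpus a `literature_corpus` (see [read_corpus()]) or list of
#'   [literature_document()]s.
#' @param drug_lex a [drug_lexicon()]; @param se_lex a [se_lexicon()].
#' @return Object of class `lit_index`: list with data.tables
#'   `drug_postings` and `se_postings` (`term`, `doc_id`, `sentence_index`,
#'   one row per occurrence sentence), `sentences` (`doc_id`,
#'   `sentence_index`, `text`) kept for pluggable sentence filters, and
#'   `n_docs`.
#' @export
build_index <- function(corpus, drug_lex, se_lex) {
  stopifnot(inherits(drug_lex, "drug_lexicon"), inherits(se_lex, "se_lexicon"))
  doc_ids <- vapply(corpus, `[[`, character(1), "doc_id")
  n_sent <- vapply(corpus, function(d) length(d$sentences), integer(1))
  sent <- data.table(
    doc_id = rep(doc_ids, n_sent),
    sentence_index = unlist(lapply(n_sent, function(k) seq_len(k) - 1L), use.names = FALSE),
    text = unlist(lapply(corpus, `[[`, "sentences"), use.names = FALSE))
  if (nrow(sent) == 0L) {
    empty <- data.table(term = character(0), doc_id = character(0),
                        sentence_index = integer(0))
    return(structure(list(drug_postings = empty, se_postings = data.table::copy(empty),
                          sentences = sent, n_docs = length(corpus)),
                     class = "lit_index"))
  }
  ddict <- pb_drug_dict(drug_lex)
  sdict <- pb_dict_build(se_lex$terms)
  toks <- pb_tokenize(pb_normalize(sent$text))
  post <- function(dict) {
    hits <- lapply(toks, function(t) unique(pb_match_tokens(t, dict)$canonical))
    k <- lengths(hits)
    out <- data.table(term = unlist(hits, use.names = FALSE),
                      doc_id = rep(sent$doc_id, k),
                      sentence_index = rep(sent$sentence_index, k))
    setorder(out, term, doc_id, sentence_index)
    out
  }
  structure(list(drug_postings = post(ddict), se_postings = post(sdict),
                 sentences = sent, n_docs = length(corpus)),
            class = "lit_index")
}

#' Sentence- and abstract-level co-occurrence evidence for pairs
#'
#' For each queried drug--side-effect pair, counts the sentences in which the
#' drug and the side-effect term co-occur (sentence level) and the documents
#' in which both occur anywhere (abstract level). Sentence-level evidence
#' implies abstract-level evidence.
#'
#' The optional `sentence_filter` hook restricts which co-occurrence
#' sentences count as evidence — e.g. a syntactic filter requiring both terms
#' to be noun phrases could be attached here. The default (no filter) counts
#' every co-occurrence sentence, so a sentence like "baclofen decreased
#' activity during the test" yields evidence for the pair
#' (baclofen, decreased activity) even though the match is not a true
#' side-effect mention; see the package vignette for this known limitation.
#'
#' @param pairs data.frame/data.table with columns `drug`, `se` (e.g. the
#'   `pairs` table of a `pair_counts`); queries are normalized.
#' @param index a `lit_index` from [build_index()].
#' @param sentence_filter optional `function(text, drug, se)` returning
#'   `TRUE` to keep a co-occurrence sentence as evidence.
#' @return Object of class `literature_evidence`: list with data.tables
#'   `sentence` and `abstract` (`drug`, `se`, `count`; only pairs with
#'   `count > 0` are stored) and `n_pairs_queried`.
#' @export
evidence_for <- function(pairs, index, sentence_filter = NULL) {
  stopifnot(inherits(index, "lit_index"))
  q <- unique(data.table(drug = pb_normalize(pairs$drug), se = pb_normalize(pairs$se)))
  dp <- index$drug_postings; sp <- index$se_postings
  # only terms that can answer a query
  dp <- dp[dp$term %in% unique(q$drug)]
  sp <- sp[sp$term %in% unique(q$se)]

  co_sent <- merge(dp, sp, by = c("doc_id", "sentence_index"),
                   allow.cartesian = TRUE, suffixes = c(".drug", ".se"))
  setnames(co_sent, c("term.drug", "term.se"), c("drug", "se"))
  co_sent <- co_sent[pb_pair_key(drug, se) %in% pb_pair_key(q$drug, q$se)]
  if (!is.null(sentence_filter) && nrow(co_sent)) {
    co_sent <- merge(co_sent, index$sentences, by = c("doc_id", "sentence_index"))
    keep <- mapply(sentence_filter, co_sent$text, co_sent$drug, co_sent$se)
    co_sent <- co_sent[as.logical(keep)]
  }
  sent_counts <- if (nrow(co_sent)) {
    unique(co_sent[, c("drug", "se", "doc_id", "sentence_index"), with = FALSE])[
      , list(count = .N), by = c("drug", "se")]
  } else data.table(drug = character(0), se = character(0), count = integer(0))

  dd <- unique(dp[, c("term", "doc_id"), with = FALSE]); setnames(dd, "term", "drug")
  sd <- unique(sp[, c("term", "doc_id"), with = FALSE]); setnames(sd, "term", "se")
  co_doc <- merge(dd, sd, by = "doc_id", allow.cartesian = TRUE)
  co_doc <- co_doc[pb_pair_key(drug, se) %in% pb_pair_key(q$drug, q$se)]
  abs_counts <- if (nrow(co_doc)) {
    co_doc[, list(count = .N), by = c("drug", "se")]
  } else data.table(drug = character(0), se = character(0), count = integer(0))

  setorder(sent_counts, drug, se); setorder(abs_counts, drug, se)
  structure(list(sentence = sent_counts, abstract = abs_counts,
                 n_pairs_queried = nrow(q)),
            class = "literature_evidence")
}

#' Pairs with co-occurrence evidence at a level
#'
#' @param ev a `literature_evidence` from [evidence_for()].
#' @param level `"sentence"` or `"abstract"`.
#' @return data.table (`drug`, `se`) of pairs with positive count at that
#'   level. The sentence set is always a subset of the abstract set.
#' @export
evidence_set <- function(ev, level = c("sentence", "abstract")) {
  stopifnot(inherits(ev, "literature_evidence"))
  level <- tryCatch(match.arg(level),
                    error = function(e) pb_config_error(paste0("unknown evidence level: '",
                                                               level[1], "'")))
  t <- ev[[level]]
  out <- unique(t[t$count > 0, c("drug", "se"), with = FALSE])
  setorder(out, drug, se)
  out[]
}

#' @export
print.literature_evidence <- function(x, ...) {
  cat("<literature_evidence> ", nrow(x$sentence), " pairs at sentence level, ",
      nrow(x$abstract), " at abstract level (", x$n_pairs_queried,
      " pairs queried)\n", sep = "")
  invisible(x)
}
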