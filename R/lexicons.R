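#' Construct a drug lexicon
#'
#' A drug lexicon holds the canonical generic drug names plus a mapping from
#' trade names to generics, the two ingredients of dictionary-based drug
#' recognition. All names are normalized with [pb_normalize()]; every trade
#' name maps to exactly one generic and every mapping target must itself be a
#' generic.
#'
#' @param generics character vector of generic drug names.
#' @param trade_to_generic named character vector: names are trade names,
#'   values the corresponding generic names. May be empty.
#' @return An object of class `drug_lexicon` with elements `generics`
#'   (sorted unique character) and `trade_to_generic` (named character).
#' @examples
#' lex <- drug_lexicon("cetuximab", c(erbitux = "cetuximab"))
#' lex$trade_to_generic[["erbitux"]]
#' @export
drug_lexicon <- function(generics, trade_to_generic = character(0)) {
  generics <- sort(unique(pb_normalize(generics)))
  generics <- generics[nzchar(generics)]
  if (length(trade_to_generic)) {
    trades <- pb_normalize(names(trade_to_generic))
    targets <- pb_normalize(unname(trade_to_generic))
    keep <- nzchar(trades)
    trades <- trades[keep]; targets <- targets[keep]
    # conflicting duplicates resolve to the lexicographically smallest generic
    if (anyDuplicated(trades)) {
      o <- order(trades, targets)
      trades <- trades[o]; targets <- targets[o]
      dup <- duplicated(trades)
      if (any(targets[dup] != targets[match(trades[dup], trades)])) {
        warning("conflicting trade-name mappings resolved to the lexicographically smallest generic",
                call. = FALSE)
      }
      targets <- targets[!dup]; trades <- trades[!dup]
    }
    missing <- setdiff(unique(targets), generics)
    if (length(missing)) {
      pb_validation_error(paste0(
        "trade names map to generics absent from the lexicon: ",
        paste(utils::head(missing, 5), collapse = ", ")))
    }
    o <- order(trades)  # canonical order so construction and file round-trips agree
    trade_to_generic <- stats::setNames(targets[o], trades[o])
  } else {
    trade_to_generic <- stats::setNames(character(0), character(0))
  }
  structure(list(generics = generics, trade_to_generic = trade_to_generic),
            class = "drug_lexicon")
}

#' Construct a side-effect lexicon
#'
#' A cleaned adverse-event term list (MedDRA-derived) with optional category
#' ancestry per term. Category subsets (e.g. all cardiovascular terms) are
#' derived only through the ancestry, see [se_subset()].
#'
#' @param terms character vector of side-effect terms.
#' @param ancestors named list mapping a term to a character vector of
#'   category labels (e.g. `"cardiac disorders"`). Terms without an entry get
#'   an empty ancestor set. Names must be a subset of `terms`.
#' @return An object of class `se_lexicon` with elements `terms` (sorted
#'   unique character) and `ancestors` (named list covering every term).
#' @export
se_lexicon <- function(terms, ancestors = list()) {
  terms <- sort(unique(pb_normalize(terms)))
  terms <- terms[nzchar(terms)]
  anc <- stats::setNames(rep(list(character(0)), length(terms)), terms)
  if (length(ancestors)) {
    keys <- pb_normalize(names(ancestors))
    bad <- setdiff(keys, terms)
    if (length(bad)) {
      pb_validation_error(paste0("ancestor entries for terms not in the lexicon: ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
    }
    for (i in seq_along(keys)) {
      anc[[keys[i]]] <- sort(unique(pb_normalize(ancestors[[i]])))
    }
  }
  structure(list(terms = terms, ancestors = anc), class = "se_lexicon")
}

#' Subset side-effect terms by category ancestry
#'
#' Returns the lexicon terms having at least one of the requested ancestor
#' categories — e.g. the cardiovascular subset is
#' `se_subset(lex, c("cardiac disorders", "vascular disorders"))`.
#'
#' @param lex a [se_lexicon()].
#' @param categories character vector of category labels.
#' @return character vector of matching terms (sorted).
#' @export
se_subset <- function(lex, categories) {
  stopifnot(inherits(lex, "se_lexicon"))
  categories <- pb_normalize(categories)
  hit <- vapply(lex$ancestors, function(a) any(a %in% categories), logical(1))
  lex$terms[lex$terms %in% names(hit)[hit]]
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat("<drug_lexicon> ", length(x$generics), " generics, ",
      length(x$trade_to_generic), " trade-name mappings\n", sep = "")
  invisible(x)
}

#' @export
print.se_lexicon <- function(x, ...) {
  n_anc <- sum(lengths(x$ancestors) > 0)
  cat("<se_lexicon> ", length(x$terms), " terms (", n_anc,
      " with category ancestry)\n", sep = "")
  invisible(x)
}
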