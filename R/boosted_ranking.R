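#' Boost a base signal for literature-supported pairs
#'
#' The boosting rule: a pair that also co-occurs in the literature has its
#' ranking score replaced by the square of its original signal; a pair seen
#' in the reports only keeps its original signal. Undefined signals (`NA`)
#' pass through unchanged.
#'
#' Note that squaring a base value in (0, 1) decreases it; [rank_pairs()]
#' warns when that happens and offers a clearly-labelled sensitivity variant
#' (`boost_floor`) that squares `max(value, 1)` instead.
#'
#' @param value numeric vector of base signal values.
#' @param has_evidence logical vector: pair co-occurs in the literature.
#' @return numeric vector of boosted values.
#' @examples
#' boost(17306, TRUE)   # 299497636
#' boost(17306, FALSE)  # 17306
#' @export
boost <- function(value, has_evidence) {
  stopifnot(length(value) == length(has_evidence))
  ifelse(has_evidence & !is.na(value), value^2, value)
}

#' Rank all pairs by a (possibly boosted) signal
#'
#' Produces the total ranking used for evaluation: every scored pair appears
#' exactly once (nothing is filtered out), ordered by boosted value
#' descending. Ties break deterministically: co-report count (`n`)
#' descending, then drug, then side effect, lexicographic. Pairs with an
#' undefined signal sort after all defined pairs, ordered by the same
#' tie-break.
#'
#' @param scores a `signal_scores` table from [score_all()].
#' @param ev a `literature_evidence` from [evidence_for()], or `NULL` for an
#'   unboosted ranking.
#' @param level evidence level, `"sentence"` or `"abstract"`.
#' @param boost_floor if `TRUE`, squares `max(value, 1)` for evidence pairs —
#'   a sensitivity-analysis variant preventing sub-1 signals from being
#'   demoted by squaring; the default `FALSE` applies the plain squaring
#'   rule.
#' @return Object of class `ranked_pairs`: data.table with columns `drug`,
#'   `se`, `base_value`, `boosted_value`, `evidence_flag`, `n`, ordered by
#'   rank; attributes `method` and `level`.
#' @export
rank_pairs <- function(scores, ev = NULL, level = c("sentence", "abstract"),
                       boost_floor = FALSE) {
  stopifnot(inherits(scores, "signal_scores"))
  level <- match.arg(level)
  t <- data.table(drug = scores$drug, se = scores$se, base_value = scores$value,
                  n = scores$n)
  if (anyDuplicated(t[, c("drug", "se")])) {
    pb_validation_error("duplicate pair in scores")
  }
  if (is.null(ev)) {
    t[, evidence_flag := FALSE]
  } else {
    es <- evidence_set(ev, level)
    t[, evidence_flag := pb_pair_key(drug, se) %in% pb_pair_key(es$drug, es$se)]
  }
  if (boost_floor) {
    t[, boosted_value := boost(pmax(base_value, 1), evidence_flag)]
  } else {
    n_demoted <- sum(t$evidence_flag & !is.na(t$base_value) & t$base_value < 1)
    if (n_demoted > 0) {
      warning(n_demoted, " evidence pair(s) have base signal < 1; squaring demotes them",
              call. = FALSE)
    }
    t[, boosted_value := boost(base_value, evidence_flag)]
  }
  setorder(t, -boosted_value, -n, drug, se, na.last = TRUE)
  out <- t[, c("drug", "se", "base_value", "boosted_value", "evidence_flag", "n"),
           with = FALSE]
  structure(out, class = c("ranked_pairs", class(out)),
            method = scores$method[1], level = if (is.null(ev)) NA_character_ else level)
}

#' Write / read a ranked pair list
#'
#' @param ranked a `ranked_pairs` table.
#' @param path output TSV.
#' @return `write_ranked` invisibly returns `path`; `read_ranked` returns a
#'   `ranked_pairs` table (rank order = file order).
#' @export
write_ranked <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_pairs"))
  fwrite(ranked, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_ranked
#' @export
read_ranked <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("drug", "se", "base_value", "boosted_value", "evidence_flag", "n")
  if (!all(need %in% names(dt))) {
    pb_format_error(paste0("ranked list needs columns ", paste(need, collapse = ", ")),
                    file = path, line = 1L)
  }
  structure(dt, class = c("ranked_pairs", class(dt)))
}
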