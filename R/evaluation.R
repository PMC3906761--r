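#' Precision, recall and F1 of a pair set against a gold standard
#'
#' @param extracted data.frame/data.table with columns `drug`, `se` (set
#'   semantics; duplicates collapse).
#' @param gold a [gold_standard()].
#' @return Object of class `set_metrics`: list with `precision` (`NA` if
#'   `extracted` is empty), `recall`, `f1`, and counts `tp`, `fp`, `fn`.
#'   `f1 = 2PR/(P+R)` when `P + R > 0`, else 0.
#' @export
set_metrics <- function(extracted, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  ex <- unique(pb_pair_key(pb_normalize(extracted$drug), pb_normalize(extracted$se)))
  gk <- pb_pair_key(gold$drug, gold$se)
  tp <- sum(ex %in% gk)
  fp <- length(ex) - tp
  fn <- length(gk) - tp
  precision <- if (length(ex)) tp / length(ex) else NA_real_
  recall <- if (length(gk)) tp / length(gk) else 0
  structure(list(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall),
                 tp = tp, fp = fp, fn = fn),
            class = "set_metrics")
}

#' F1 score from precision and recall
#'
#' `2PR/(P+R)`, 0 when `P + R = 0`, `NA` when precision is undefined.
#' @param precision,recall numeric scalars or vectors.
#' @return numeric.
#' @examples
#' f1_score(0.140, 0.138)  # ~0.139
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall), NA_real_,
         ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0))
}

#' 11-point interpolated precision-recall curve of a ranked list
#'
#' Walks the ranked list top-down; at rank k, recall is the fraction of gold
#' pairs retrieved and precision the fraction of retrieved pairs that are
#' gold. The interpolated precision at recall level r is the maximum
#' precision at any rank whose recall is >= r, measured at the 11 levels
#' 0.0, 0.1, ..., 1.0; the average precision is the arithmetic mean of the
#' 11 values.
#'
#' By default the recall denominator is the reachable gold — the gold pairs
#' that occur anywhere in the ranked list — which compares ranking methods on
#' the same candidate universe. With
#' `recall_denominator = "full"` the denominator is the whole gold standard
#' and levels above the maximum attainable recall get interpolated
#' precision 0.
#'
#' @param ranked a `ranked_pairs` table (or any data.frame with columns
#'   `drug`, `se` in rank order).
#' @param gold a [gold_standard()].
#' @param recall_denominator `"reachable"` (default) or `"full"`.
#' @return Object of class `pr_curve`: list with `recall_levels` (the 11
#'   levels), `interp_precision` (11 non-increasing values), and
#'   `average_precision`. If no gold pair occurs in the ranked list the
#'   curve is undefined: all values `NA`.
#' @export
interpolated_pr <- function(ranked, gold, recall_denominator = c("reachable", "full")) {
  stopifnot(inherits(gold, "gold_standard"))
  recall_denominator <- match.arg(recall_denominator)
  levels <- seq(0, 1, by = 0.1)
  keys <- pb_pair_key(pb_normalize(ranked$drug), pb_normalize(ranked$se))
  gk <- pb_pair_key(gold$drug, gold$se)
  is_gold <- keys %in% gk
  n_reachable <- sum(is_gold)
  if (n_reachable == 0L) {
    return(structure(list(recall_levels = levels,
                          interp_precision = rep(NA_real_, 11L),
                          average_precision = NA_real_, n_gold_used = 0L),
                     class = "pr_curve"))
  }
  denom <- if (recall_denominator == "reachable") n_reachable else length(gk)
  tp <- cumsum(is_gold)
  k <- seq_along(keys)
  rec <- tp / denom
  prec <- tp / k
  # running max of precision from the bottom of the list upward gives, at each
  # rank, the best precision achievable at that recall or higher
  best_from <- rev(cummax(rev(prec)))
  interp <- vapply(levels, function(r) {
    i <- which(rec >= r - 1e-12)[1]
    if (is.na(i)) 0 else best_from[i]
  }, numeric(1))
  structure(list(recall_levels = levels, interp_precision = interp,
                 average_precision = mean(interp), n_gold_used = denom),
            class = "pr_curve")
}

#' Interpolated precision at one recall level
#'
#' @param curve a `pr_curve` from [interpolated_pr()].
#' @param level one of the 11 recall levels 0.0, 0.1, ..., 1.0.
#' @return the interpolated precision at that level.
#' @export
precision_at_recall <- function(curve, level) {
  stopifnot(inherits(curve, "pr_curve"))
  i <- which(abs(curve$recall_levels - level) < 1e-9)
  if (length(i) != 1L) {
    pb_validation_error(paste0("recall level must be one of 0.0, 0.1, ..., 1.0; got ", level))
  }
  curve$interp_precision[i]
}

#' Relative change between two metric values
#'
#' `(new - base) / base`, reported also as a fold change rounded to 1
#' decimal and a percent change rounded to integer — e.g. a precision rising
#' from 0.025 to 0.278 is a 10.1-fold (1012\%) elevation.
#'
#' @param new,base numeric scalars; `base` must be > 0.
#' @return list with `change` (the raw fraction), `fold` (1 decimal),
#'   `percent` (integer).
#' @export
relative_change <- function(new, base) {
  if (!is.numeric(base) || base <= 0) pb_validation_error("base must be > 0")
  change <- (new - base) / base
  list(change = change, fold = round(change, 1), percent = round(change * 100))
}

#' Construct curated pair labels
#'
#' A total three-way classification of a curated pair set into causal
#' side-effect pairs (`CAUSE`), drug-disease treatment pairs (`TREAT`) and
#' pairs with no direct semantic relationship (`NONE`).
#'
#' @param drug,se character vectors (the pairs).
#' @param label character vector in `{"CAUSE", "TREAT", "NONE"}`.
#' @return Object of class `curation_labels`: data.table `drug`, `se`,
#'   `label`, unique pairs.
#' @export
curation_labels <- function(drug, se, label) {
  label <- toupper(label)
  if (!all(label %in% c("CAUSE", "TREAT", "NONE"))) {
    pb_validation_error("labels must be CAUSE, TREAT or NONE")
  }
  dt <- data.table(drug = pb_normalize(drug), se = pb_normalize(se), label = label)
  if (anyDuplicated(dt[, c("drug", "se")])) {
    pb_validation_error("curation labels must partition the pair set (duplicate pair)")
  }
  setorder(dt, drug, se)
  structure(dt, class = c("curation_labels", class(dt)))
}

#' Precision and novelty of a curated pair set
#'
#' Treats the `CAUSE` class as the true positives of the curated set:
#' precision is the fraction of curated pairs labelled `CAUSE`, and novelty
#' is the fraction of `CAUSE` pairs absent from the gold standard — the
#' candidate signals not yet captured by drug labels.
#'
#' @param labels a [curation_labels()] table.
#' @param gold a [gold_standard()].
#' @return list with `n`, `precision` (= CAUSE fraction), `fraction_treat`,
#'   `fraction_none`, `n_cause`, `n_cause_novel`, `novelty` (fraction of
#'   CAUSE pairs not in gold).
#' @export
curation_metrics <- function(labels, gold) {
  stopifnot(inherits(labels, "curation_labels"), inherits(gold, "gold_standard"))
  if (nrow(labels) == 0L) pb_validation_error("labels must be nonempty")
  n <- nrow(labels)
  cause <- labels[labels$label == "CAUSE"]
  gk <- pb_pair_key(gold$drug, gold$se)
  novel <- sum(!pb_pair_key(cause$drug, cause$se) %in% gk)
  list(n = n,
       precision = nrow(cause) / n,
       fraction_treat = sum(labels$label == "TREAT") / n,
       fraction_none = sum(labels$label == "NONE") / n,
       n_cause = nrow(cause),
       n_cause_novel = novel,
       novelty = if (nrow(cause)) novel / nrow(cause) else NA_real_)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat("<pr_curve> 11-point interpolated precision; AP = ",
      format(x$average_precision, digits = 4), "\n", sep = "")
  print(stats::setNames(round(x$interp_precision, 4), format(x$recall_levels)))
  invisible(x)
}

#' @export
print.set_metrics <- function(x, ...) {
  cat(sprintf("<set_metrics> P = %.3f, R = %.3f, F1 = %.3f (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}
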