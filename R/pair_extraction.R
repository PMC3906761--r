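#' Extract drug--side-effect pair counts from spontaneous reports
#'
#' Runs entity recognition on every report: the free-text drug strings yield
#' a set of distinct generic drugs, the coded event strings a set of distinct
#' side-effect terms. If a report carries m recognized drugs and n recognized
#' events, all m x n pairs are counted — once per report, regardless of how
#' often a drug or event is mentioned within it. Marginals are report-level:
#' the number of reports containing the drug (resp. the side effect).
#'
#' The contingency universe `N` is the number of reports with at least one
#' recognized drug AND at least one recognized event; reports recognized on
#' one side only are excluded from `N` and from the marginals, which keeps
#' every 2x2 table summing to `N` with non-negative cells. Exclusion counts
#' are reported in `$stats`.
#'
#' @param reports a `report_set` (see [read_reports()]) or list of
#'   [report_record()]s.
#' @param drug_lex a [drug_lexicon()].
#' @param se_lex a [se_lexicon()].
#' @return Object of class `pair_counts`: list with
#'   \item{pairs}{data.table `(drug, se, n)` — reports containing both}
#'   \item{drug_marginals}{data.table `(drug, n)`}
#'   \item{se_marginals}{data.table `(se, n)`}
#'   \item{N}{integer universe size}
#'   \item{stats}{per-run counts: total reports, reports with no recognized
#'     drug / event, unmatched drug strings}
#' @export
extract_pairs <- function(reports, drug_lex, se_lex) {
  stopifnot(inherits(drug_lex, "drug_lexicon"), inherits(se_lex, "se_lexicon"))
  dict <- pb_drug_dict(drug_lex)

  n_rep <- length(reports)
  d_strings <- lapply(reports, `[[`, "drug_strings")
  e_strings <- lapply(reports, `[[`, "event_terms")

  flat_d <- unlist(d_strings, use.names = FALSE)
  ents <- pb_ner_entities(if (is.null(flat_d)) character(0) else flat_d, dict)
  n_unmatched_drug_strings <- sum(lengths(ents) == 0L)
  d_per_report <- split(ents, rep(seq_len(n_rep), lengths(d_strings)))
  D <- rep(list(character(0)), n_rep)
  idx <- as.integer(names(d_per_report))
  D[idx] <- lapply(d_per_report, function(e) unique(unlist(e, use.names = FALSE)))

  flat_e <- unlist(e_strings, use.names = FALSE)
  norm_e <- pb_normalize(if (is.null(flat_e)) character(0) else flat_e)
  keep_e <- norm_e %in% se_lex$terms
  se_hit <- ifelse(keep_e, norm_e, NA_character_)
  e_per_report <- split(se_hit, rep(seq_len(n_rep), lengths(e_strings)))
  S <- rep(list(character(0)), n_rep)
  idx <- as.integer(names(e_per_report))
  S[idx] <- lapply(e_per_report, function(e) unique(e[!is.na(e)]))

  nd <- lengths(D); ns <- lengths(S)
  in_universe <- nd > 0L & ns > 0L
  N <- sum(in_universe)
  Du <- D[in_universe]; Su <- S[in_universe]
  ndu <- nd[in_universe]; nsu <- ns[in_universe]

  if (N > 0L) {
    drug_col <- unlist(lapply(seq_len(N), function(i) rep(Du[[i]], each = nsu[i])),
                       use.names = FALSE)
    se_col <- unlist(lapply(seq_len(N), function(i) rep(Su[[i]], times = ndu[i])),
                     use.names = FALSE)
    pairs <- data.table(drug = drug_col, se = se_col)[, list(n = .N), by = c("drug", "se")]
    dm <- data.table(drug = unlist(Du, use.names = FALSE))[, list(n = .N), by = "drug"]
    sm <- data.table(se = unlist(Su, use.names = FALSE))[, list(n = .N), by = "se"]
  } else {
    pairs <- data.table(drug = character(0), se = character(0), n = integer(0))
    dm <- data.table(drug = character(0), n = integer(0))
    sm <- data.table(se = character(0), n = integer(0))
  }
  setorder(pairs, drug, se); setorder(dm, drug); setorder(sm, se)

  structure(list(
    pairs = pairs, drug_marginals = dm, se_marginals = sm, N = N,
    stats = list(n_reports = n_rep,
                 n_reports_no_drug = sum(nd == 0L),
                 n_reports_no_se = sum(ns == 0L),
                 n_reports_excluded = n_rep - N,
                 n_unmatched_drug_strings = n_unmatched_drug_strings)),
    class = "pair_counts")
}

#' 2x2 contingency table for one drug--side-effect pair
#'
#' Cells count reports in the extraction universe: `a` with both drug and
#' side effect, `b` with the drug but not the side effect, `c` with the side
#' effect but not the drug, `d` with neither; `a + b + c + d = N` for every
#' pair of one dataset.
#'
#' @param pc a `pair_counts` object from [extract_pairs()].
#' @param drug,se the pair (normalized or raw; normalization is applied).
#' @return Object of class `contingency_table`: list with integer cells
#'   `a`, `b`, `c`, `d` and `N`.
#' @export
contingency <- function(pc, drug, se) {
  stopifnot(inherits(pc, "pair_counts"))
  drug <- pb_normalize(drug); se <- pb_normalize(se)
  a <- pc$pairs$n[pc$pairs$drug == drug & pc$pairs$se == se]
  a <- if (length(a)) a[1] else 0L
  n_drug <- pc$drug_marginals$n[pc$drug_marginals$drug == drug]
  n_drug <- if (length(n_drug)) n_drug[1] else 0L
  n_se <- pc$se_marginals$n[pc$se_marginals$se == se]
  n_se <- if (length(n_se)) n_se[1] else 0L
  contingency_table(a, n_drug - a, n_se - a, pc$N - n_drug - n_se + a)
}

#' Construct a contingency table from its four cells
#'
#' @param a,b,c,d non-negative integer cell counts (drug&SE, drug only,
#'   SE only, neither). Negative cells raise an internal-consistency error.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) {
    pb_internal_error(paste0("negative or missing contingency cell: (",
                             paste(cells, collapse = ", "), ")"))
  }
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "contingency_table")
}

# all pairs with marginals attached, one row per pair: columns
# drug, se, a, b, c, d (vectorized input to the signal functions)
pb_contingency_all <- function(pc) {
  stopifnot(inherits(pc, "pair_counts"))
  t <- data.table::copy(pc$pairs)
  t[pc$drug_marginals, on = "drug", n_drug := i.n]
  t[pc$se_marginals, on = "se", n_se := i.n]
  t[, `:=`(a = as.numeric(n), b = as.numeric(n_drug - n), c = as.numeric(n_se - n),
           d = as.numeric(pc$N - n_drug - n_se + n))]
  if (nrow(t) && (min(t$b) < 0L || min(t$c) < 0L || min(t$d) < 0L)) {
    pb_internal_error("inconsistent pair counts produced a negative contingency cell")
  }
  t[, c("drug", "se", "a", "b", "c", "d"), with = FALSE]
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("<pair_counts> ", nrow(x$pairs), " distinct pairs, ",
      nrow(x$drug_marginals), " drugs, ", nrow(x$se_marginals),
      " side effects, N = ", x$N, " reports\n", sep = "")
  invisible(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "no drug"), c("SE", "no SE")))
  print(m)
  invisible(x)
}
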