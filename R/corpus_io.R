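#' @importFrom data.table data.table fread fwrite setnames setorder rbindlist as.data.table :=
NULL

# internal key for pair-set operations; \t cannot occur in normalized terms
pb_pair_key <- function(drug, se) paste(drug, se, sep = "\t")

#' Construct a spontaneous-report record
#'
#' One report as assembled by joining the drug file and the reaction file on
#' the report ID. Either list may be empty: a report can appear in only one
#' of the two files.
#'
#' @param report_id nonempty identifier string.
#' @param drug_strings character vector of free-text drug strings, in file
#'   order.
#' @param event_terms character vector of coded adverse-event terms, in file
#'   order.
#' @return An object of class `report_record`.
#' @export
report_record <- function(report_id, drug_strings = character(0),
                          event_terms = character(0)) {
  report_id <- as.character(report_id)
  if (length(report_id) != 1L || is.na(report_id) || !nzchar(report_id)) {
    pb_validation_error("report_id must be a single nonempty string")
  }
  structure(list(report_id = report_id,
                 drug_strings = as.character(drug_strings),
                 event_terms = as.character(event_terms)),
            class = "report_record")
}

# Read one side (DRUG or REAC) of a spontaneous-report quarter file.
# Returns data.table(report_id, value) with empty-ID rows dropped; the number
# dropped is in attr "n_skipped".
pb_read_report_side <- function(files, dialect, value_cols) {
  sep <- switch(dialect, faers_dollar = "$", tsv = "\t",
                pb_config_error(paste0("unknown report dialect: '", dialect, "'")))
  parts <- vector("list", length(files))
  n_skipped <- 0L
  for (i in seq_along(files)) {
    f <- files[i]
    if (!file.exists(f)) pb_validation_error(paste0("input file does not exist: ", f))
    dt <- tryCatch(
      fread(f, sep = sep, header = TRUE, colClasses = "character",
            quote = "", fill = TRUE, blank.lines.skip = TRUE),
      error = function(e) pb_format_error(paste0("cannot parse header/rows: ",
                                                 conditionMessage(e)), file = f, line = 1L))
    if (ncol(dt) < 2L) {
      pb_format_error("header must declare at least a report-ID column and a value column",
                      file = f, line = 1L)
    }
    nm <- tolower(names(dt))
    id_col <- which(nm %in% c("isr", "primaryid", "report_id", "id"))[1]
    if (is.na(id_col)) id_col <- 1L
    val_col <- which(nm %in% value_cols)[1]
    if (is.na(val_col)) val_col <- if (id_col == 1L) 2L else 1L
    out <- dt[, c(id_col, val_col), with = FALSE]
    setnames(out, c("report_id", "value"))
    bad <- is.na(out$report_id) | !nzchar(trimws(out$report_id))
    n_skipped <- n_skipped + sum(bad)
    parts[[i]] <- out[!bad]
  }
  res <- rbindlist(parts)
  res[, report_id := trimws(report_id)]
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Read spontaneous reports from paired drug/reaction files
#'
#' Joins drug rows and event rows on the report ID, producing one record per
#' distinct ID (outer-merge semantics: an ID present in only one file yields a
#' record with the other list empty). Rows with an empty report ID are
#' skipped and counted. IDs recurring across several quarterly files are
#' merged by union.
#'
#' @param drug_files path(s) to drug files (free-text drug strings per report).
#' @param reac_files path(s) to reaction files (coded event terms per report).
#' @param dialect `"faers_dollar"` for `$`-delimited files with a header row
#'   (the FAERS ASCII distribution layout; the report-ID column is `ISR` or
#'   `primaryid`, the value columns `DRUGNAME` / `PT`), or `"tsv"` for
#'   tab-delimited files with columns `report_id` and `drug_string` /
#'   `event_term`.
#' @return An object of class `report_set`: a list of [report_record()]s
#'   ordered by report ID, with attributes `n_skipped_drug_rows` and
#'   `n_skipped_reac_rows`.
#' @export
read_reports <- function(drug_files, reac_files, dialect = c("tsv", "faers_dollar")) {
  dialect <- dialect[1]
  if (!dialect %in% c("tsv", "faers_dollar")) {
    pb_config_error(paste0("unknown report dialect: '", dialect, "'"))
  }
  dd <- pb_read_report_side(drug_files, dialect,
                            value_cols = c("drugname", "drug_string", "drug"))
  rd <- pb_read_report_side(reac_files, dialect,
                            value_cols = c("pt", "event_term", "term", "reaction"))
  ids <- sort(unique(c(dd$report_id, rd$report_id)))
  dl <- if (nrow(dd)) dd[, list(v = list(value)), by = report_id] else NULL
  rl <- if (nrow(rd)) rd[, list(v = list(value)), by = report_id] else NULL
  di <- if (is.null(dl)) rep(NA_integer_, length(ids)) else match(ids, dl$report_id)
  ri <- if (is.null(rl)) rep(NA_integer_, length(ids)) else match(ids, rl$report_id)
  empty <- character(0)
  records <- lapply(seq_along(ids), function(i) {
    report_record(ids[i],
                  drug_strings = if (is.na(di[i])) empty else dl$v[[di[i]]],
                  event_terms  = if (is.na(ri[i])) empty else rl$v[[ri[i]]])
  })
  structure(records, class = "report_set",
            n_skipped_drug_rows = attr(dd, "n_skipped"),
            n_skipped_reac_rows = attr(rd, "n_skipped"))
}

#' Write spontaneous reports to paired drug/reaction files
#'
#' Inverse of [read_reports()]. Reports contribute a row per drug string to
#' the drug file and a row per event term to the reaction file; reports with
#' an empty list on one side are simply absent from that file.
#'
#' @param reports a `report_set` or plain list of [report_record()]s.
#' @param drug_file,reac_file output paths.
#' @param dialect see [read_reports()].
#' @return Invisibly, a character vector of the two paths.
#' @export
write_reports <- function(reports, drug_file, reac_file,
                          dialect = c("tsv", "faers_dollar")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "faers_dollar") "$" else "\t"
  ids <- vapply(reports, `[[`, character(1), "report_id")
  dd <- data.table(
    report_id = rep(ids, vapply(reports, function(r) length(r$drug_strings), integer(1))),
    value = unlist(lapply(reports, `[[`, "drug_strings"), use.names = FALSE))
  rd <- data.table(
    report_id = rep(ids, vapply(reports, function(r) length(r$event_terms), integer(1))),
    value = unlist(lapply(reports, `[[`, "event_terms"), use.names = FALSE))
  if (dialect == "faers_dollar") {
    setnames(dd, c("ISR", "DRUGNAME")); setnames(rd, c("ISR", "PT"))
  } else {
    setnames(dd, c("report_id", "drug_string")); setnames(rd, c("report_id", "event_term"))
  }
  fwrite(dd, drug_file, sep = sep, quote = FALSE)
  fwrite(rd, reac_file, sep = sep, quote = FALSE)
  invisible(c(drug_file, reac_file))
}

#' Read drug and side-effect lexicons from TSV files
#'
#' The drug file has columns `name`, `generic`, `kind` (`generic` or `trade`);
#' the side-effect file has columns `term`, `ancestors` (a `|`-separated list
#' of category labels, possibly empty). Duplicate trade names with
#' conflicting generics resolve deterministically to the lexicographically
#' smallest generic, with a warning.
#'
#' @param drug_lexicon_file,se_lexicon_file input paths.
#' @return A list with elements `drug` ([drug_lexicon()]) and
#'   `se` ([se_lexicon()]).
#' @export
read_lexicons <- function(drug_lexicon_file, se_lexicon_file) {
  dl <- fread(drug_lexicon_file, sep = "\t", header = TRUE, colClasses = "character",
              quote = "", fill = TRUE)
  if (!all(c("name", "generic", "kind") %in% names(dl))) {
    pb_format_error("drug lexicon needs columns name, generic, kind",
                    file = drug_lexicon_file, line = 1L)
  }
  if (nrow(dl) && !all(dl$kind %in% c("generic", "trade"))) {
    bad <- which(!dl$kind %in% c("generic", "trade"))[1]
    pb_format_error(paste0("kind must be 'generic' or 'trade', got '", dl$kind[bad], "'"),
                    file = drug_lexicon_file, line = bad + 1L)
  }
  generics <- dl$name[dl$kind == "generic"]
  trade <- dl[dl$kind == "trade", ]
  drug <- drug_lexicon(generics, stats::setNames(trade$generic, trade$name))

  sl <- fread(se_lexicon_file, sep = "\t", header = TRUE, colClasses = "character",
              quote = "", fill = TRUE)
  if (!("term" %in% names(sl))) {
    pb_format_error("side-effect lexicon needs a 'term' column",
                    file = se_lexicon_file, line = 1L)
  }
  anc <- list()
  if ("ancestors" %in% names(sl) && nrow(sl)) {
    has <- !is.na(sl$ancestors) & nzchar(sl$ancestors)
    anc <- stats::setNames(strsplit(sl$ancestors[has], "|", fixed = TRUE),
                           pb_normalize(sl$term[has]))
  }
  se <- se_lexicon(sl$term, anc)
  list(drug = drug, se = se)
}

#' Write drug and side-effect lexicons to TSV files
#'
#' Inverse of [read_lexicons()]; rows are written sorted so output is stable.
#'
#' @param drug_lex a [drug_lexicon()]; @param se_lex a [se_lexicon()].
#' @param drug_lexicon_file,se_lexicon_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_lexicons <- function(drug_lex, se_lex, drug_lexicon_file, se_lexicon_file) {
  dd <- rbindlist(list(
    data.table(name = drug_lex$generics, generic = drug_lex$generics, kind = "generic"),
    data.table(name = names(drug_lex$trade_to_generic),
               generic = unname(drug_lex$trade_to_generic), kind = "trade")))
  setorder(dd, kind, name)
  fwrite(dd, drug_lexicon_file, sep = "\t", quote = FALSE)
  sd <- data.table(term = se_lex$terms,
                   ancestors = vapply(se_lex$ancestors[se_lex$terms], paste,
                                      character(1), collapse = "|"))
  setorder(sd, term)
  fwrite(sd, se_lexicon_file, sep = "\t", quote = FALSE)
  invisible(c(drug_lexicon_file, se_lexicon_file))
}

#' Construct a literature document
#'
#' @param doc_id opaque document identifier (PMID-like).
#' @param sentences character vector of sentence texts in order; the abstract
#'   is their concatenation.
#' @return An object of class `literature_document`.
#' @export
literature_document <- function(doc_id, sentences) {
  doc_id <- as.character(doc_id)
  if (length(doc_id) != 1L || !nzchar(doc_id)) pb_validation_error("doc_id must be nonempty")
  structure(list(doc_id = doc_id, sentences = as.character(sentences)),
            class = "literature_document")
}

#' Read a literature corpus from a sentence-level TSV
#'
#' Input columns: `doc_id`, `sentence_index`, `text`; the sentence index must
#' be contiguous from 0 within each document (a gap is a format error).
#' Documents come back in order of first appearance.
#'
#' @param path input TSV.
#' @return A list of [literature_document()]s, class `literature_corpus`.
#' @export
read_corpus <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              quote = "", fill = TRUE)
  if (nrow(dt) == 0L) return(structure(list(), class = "literature_corpus"))
  if (!all(c("doc_id", "sentence_index", "text") %in% names(dt))) {
    pb_format_error("corpus needs columns doc_id, sentence_index, text",
                    file = path, line = 1L)
  }
  dt[, sentence_index := suppressWarnings(as.integer(sentence_index))]
  if (anyNA(dt$sentence_index)) {
    pb_format_error("non-integer sentence_index", file = path)
  }
  ids <- unique(dt$doc_id)
  rows <- split(seq_len(nrow(dt)), factor(dt$doc_id, levels = ids))
  docs <- lapply(ids, function(id) {
    r <- rows[[id]][order(dt$sentence_index[rows[[id]]])]
    if (!identical(dt$sentence_index[r], seq_along(r) - 1L)) {
      pb_format_error(paste0("sentence_index for document '", id,
                             "' is not contiguous from 0"), file = path)
    }
    literature_document(id, dt$text[r])
  })
  structure(docs, class = "literature_corpus")
}

#' Write a literature corpus to a sentence-level TSV
#'
#' Inverse of [read_corpus()].
#' @param corpus list of [literature_document()]s.
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  dt <- rbindlist(lapply(corpus, function(d) {
    data.table(doc_id = d$doc_id,
               sentence_index = seq_along(d$sentences) - 1L,
               text = d$sentences)
  }))
  if (nrow(dt) == 0L) dt <- data.table(doc_id = character(0),
                                       sentence_index = integer(0), text = character(0))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a gold standard of drug--side-effect pairs
#'
#' A deduplicated, normalized set of (generic drug, side-effect term) pairs,
#' e.g. pairs compiled from drug labels, used to compare ranking approaches.
#'
#' @param drug,se character vectors of equal length.
#' @return Object of class `gold_standard`: a data.table with columns
#'   `drug`, `se`, sorted, unique.
#' @export
gold_standard <- function(drug, se) {
  dt <- unique(data.table(drug = pb_normalize(drug), se = pb_normalize(se)))
  setorder(dt, drug, se)
  structure(dt, class = c("gold_standard", class(dt)))
}

#' Read a gold-standard pair list
#'
#' TSV with columns `drug`, `se`; duplicates are collapsed (set semantics).
#' @param path input TSV.
#' @return A [gold_standard()].
#' @export
read_gold <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              quote = "", fill = TRUE)
  if (!all(c("drug", "se") %in% names(dt))) {
    pb_format_error("gold standard needs columns drug, se", file = path, line = 1L)
  }
  gold_standard(dt$drug, dt$se)
}

#' Read an external drug--side-effect score table
#'
#' TSV with columns `drug`, `se`, `score` (numeric; scientific notation
#' accepted). A non-numeric score is a format error. Duplicated pairs keep
#' the largest score, with a warning.
#'
#' @param path input TSV.
#' @return Object of class `external_scores`: data.table with columns `drug`,
#'   `se`, `score`, sorted, one row per pair.
#' @export
read_external_scores <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              quote = "", fill = TRUE)
  if (!all(c("drug", "se", "score") %in% names(dt))) {
    pb_format_error("score table needs columns drug, se, score", file = path, line = 1L)
  }
  score <- suppressWarnings(as.numeric(dt$score))
  bad <- which(is.na(score) & !is.na(dt$score) & nzchar(dt$score))
  if (length(bad)) {
    pb_format_error(paste0("non-numeric score '", dt$score[bad[1]], "'"),
                    file = path, line = bad[1] + 1L)
  }
  if (anyNA(score) || any(!is.finite(score))) {
    pb_format_error("missing or non-finite score", file = path)
  }
  out <- data.table(drug = pb_normalize(dt$drug), se = pb_normalize(dt$se),
                    score = score)
  if (anyDuplicated(out[, c("drug", "se")])) {
    warning("duplicated pairs in score table; keeping the largest score", call. = FALSE)
    out <- out[, list(score = max(score)), by = c("drug", "se")]
  }
  setorder(out, drug, se)
  structure(out, class = c("external_scores", class(out)))
}

#' Read a plain drug--side-effect pair list
#'
#' TSV with columns `drug`, `se` and optionally `score`; normalized and
#' deduplicated.
#'
#' @param path input TSV.
#' @return data.table with columns `drug`, `se` (and `score` if present),
#'   sorted, unique.
#' @export
read_pairs <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              quote = "", fill = TRUE)
  if (!all(c("drug", "se") %in% names(dt))) {
    pb_format_error("pair list needs columns drug, se", file = path, line = 1L)
  }
  out <- data.table(drug = pb_normalize(dt$drug), se = pb_normalize(dt$se))
  if ("score" %in% names(dt)) {
    s <- suppressWarnings(as.numeric(dt$score))
    bad <- which(is.na(s) & !is.na(dt$score) & nzchar(dt$score))
    if (length(bad)) pb_format_error(paste0("non-numeric score '", dt$score[bad[1]], "'"),
                                     file = path, line = bad[1] + 1L)
    out[, score := s]
  }
  out <- unique(out)
  setorder(out, drug, se)
  out[]
}

#' Write a drug--side-effect pair list
#'
#' Writes TSV rows sorted by drug then side effect (lexicographic), so output
#' files are byte-stable and `write_pairs()` is the inverse of [read_pairs()]
#' on normalized data.
#'
#' @param pairs a data.frame/data.table with columns `drug`, `se` and
#'   optionally `score` (a [gold_standard()] or `external_scores` works).
#' @param path output TSV.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  dt <- as.data.table(pairs)
  if (!all(c("drug", "se") %in% names(dt))) {
    pb_validation_error("pairs must have columns drug, se")
  }
  cols <- intersect(c("drug", "se", "score"), names(dt))
  dt <- unique(dt[, cols, with = FALSE])
  setorder(dt, drug, se)
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", length(x), " reports\n", sep = "")
  invisible(x)
}
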