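# rolling polynomial hash (mod 2^31-1) of the serialized config; embedded in
# outputs so a ranked list can be traced back to the configuration that made it
pb_config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble and validate a pipeline configuration
#'
#' @param drug_files,reac_files report input files (see [read_reports()]).
#' @param drug_lexicon,se_lexicon lexicon TSV paths (see [read_lexicons()]).
#' @param corpus literature corpus TSV path.
#' @param gold gold-standard TSV path.
#' @param external_scores optional external score table TSV path (required
#'   when `method = "external"`).
#' @param outdir output directory.
#' @param dialect report-file dialect, `"tsv"` or `"faers_dollar"`.
#' @param method ranking method (see [score_all()]).
#' @param level evidence level, `"sentence"` or `"abstract"`.
#' @param boost_floor see [rank_pairs()].
#' @param ic_mode see [score_all()].
#' @param recall_denominator see [interpolated_pr()].
#' @return Object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(drug_files, reac_files, drug_lexicon, se_lexicon,
                            corpus, gold, external_scores = NULL, outdir,
                            dialect = "tsv", method = "freq", level = "sentence",
                            boost_floor = FALSE, ic_mode = "raw",
                            recall_denominator = "reachable") {
  cfg <- list(drug_files = drug_files, reac_files = reac_files,
              drug_lexicon = drug_lexicon, se_lexicon = se_lexicon,
              corpus = corpus, gold = gold, external_scores = external_scores,
              outdir = outdir, dialect = dialect, method = method, level = level,
              boost_floor = isTRUE(boost_floor), ic_mode = ic_mode,
              recall_denominator = recall_denominator)
  if (!dialect %in% c("tsv", "faers_dollar")) {
    pb_config_error(paste0("unknown dialect: '", dialect, "'"))
  }
  if (!method %in% c("freq", "prr", "rrr", "ror", "phi", "ic", "external")) {
    pb_config_error(paste0("unknown method: '", method, "'"))
  }
  if (!level %in% c("sentence", "abstract")) {
    pb_config_error(paste0("unknown evidence level: '", level, "'"))
  }
  if (method == "external" && is.null(external_scores)) {
    pb_validation_error("method 'external' needs an external_scores file")
  }
  req <- c(drug_files, reac_files, drug_lexicon, se_lexicon, corpus, gold,
           external_scores)
  missing <- req[!file.exists(req)]
  if (length(missing)) {
    pb_validation_error(paste0("input file(s) not found: ",
                               paste(missing, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes the end-to-end flow: read reports and lexicons, extract
#' drug--side-effect pair counts (extract), score every pair with the chosen
#' method (score), find literature co-occurrence evidence (match-literature),
#' boost and rank (boost), and evaluate the unboosted and boosted rankings
#' against the gold standard (evaluate). Writes `ranked.tsv`,
#' `evaluation.json` and `run_log.txt` into `outdir`; all outputs embed the
#' configuration hash. Rerunning with the same config gives identical
#' outputs (the pipeline itself draws no random numbers).
#'
#' @param cfg a [pipeline_config()], or a path to a YAML file whose fields
#'   are the [pipeline_config()] arguments.
#' @return list with elements `counts` (per-stage counts), `metrics`
#'   (set-level precision/recall/F1 for all pairs and for the
#'   evidence-restricted sets), `curves` (`pr_curve`s for the base and
#'   boosted rankings plus their average precisions), `ranked`
#'   (the boosted `ranked_pairs`), `config_hash`, and `paths` of the files
#'   written.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- do.call(pipeline_config, yaml::read_yaml(cfg))
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  hash <- pb_config_hash(unclass(cfg))
  log_lines <- c(paste0("pharmaboost run ", hash),
                 paste0("method=", cfg$method, " level=", cfg$level))

  stage <- function(name, expr) {
    tryCatch(expr, pb_error = function(e) {
      pb_stop(class(e)[1], paste0("stage '", name, "': ", conditionMessage(e)))
    })
  }

  reports <- stage("extract", read_reports(cfg$drug_files, cfg$reac_files, cfg$dialect))
  lex <- stage("extract", read_lexicons(cfg$drug_lexicon, cfg$se_lexicon))
  pc <- stage("extract", extract_pairs(reports, lex$drug, lex$se))
  log_lines <- c(log_lines,
                 sprintf("reports read: %d (universe N = %d; no drug: %d, no SE: %d)",
                         pc$stats$n_reports, pc$N, pc$stats$n_reports_no_drug,
                         pc$stats$n_reports_no_se),
                 sprintf("pairs extracted: %d", nrow(pc$pairs)))

  ext <- if (!is.null(cfg$external_scores)) {
    stage("score", read_external_scores(cfg$external_scores))
  } else NULL
  scores <- stage("score", score_all(pc, cfg$method, external = ext,
                                     ic_mode = cfg$ic_mode))

  corpus <- stage("match-literature", read_corpus(cfg$corpus))
  index <- stage("match-literature", build_index(corpus, lex$drug, lex$se))
  ev <- stage("match-literature", evidence_for(pc$pairs, index))
  n_sent <- nrow(evidence_set(ev, "sentence"))
  n_abs <- nrow(evidence_set(ev, "abstract"))
  log_lines <- c(log_lines,
                 sprintf("pairs with evidence: sentence %d, abstract %d", n_sent, n_abs))

  ranked_base <- stage("boost", rank_pairs(scores, ev = NULL))
  ranked <- stage("boost", rank_pairs(scores, ev = ev, level = cfg$level,
                                      boost_floor = cfg$boost_floor))

  gold <- stage("evaluate", read_gold(cfg$gold))
  m_all <- set_metrics(pc$pairs, gold)
  m_sent <- set_metrics(evidence_set(ev, "sentence"), gold)
  m_abs <- set_metrics(evidence_set(ev, "abstract"), gold)
  curve_base <- interpolated_pr(ranked_base, gold, cfg$recall_denominator)
  curve_boosted <- interpolated_pr(ranked, gold, cfg$recall_denominator)
  if (is.na(curve_base$average_precision)) {
    log_lines <- c(log_lines, "WARNING: no gold pair occurs among extracted pairs; curves undefined")
  }

  paths <- list(ranked = file.path(cfg$outdir, "ranked.tsv"),
                evaluation = file.path(cfg$outdir, "evaluation.json"),
                log = file.path(cfg$outdir, "run_log.txt"))
  write_ranked(ranked, paths$ranked)
  report <- list(
    config_hash = hash,
    config = unclass(cfg),
    counts = list(n_reports = pc$stats$n_reports, N = pc$N,
                  n_pairs = nrow(pc$pairs),
                  n_evidence_sentence = n_sent, n_evidence_abstract = n_abs),
    set_metrics = list(all = unclass(m_all),
                       evidence_sentence = unclass(m_sent),
                       evidence_abstract = unclass(m_abs)),
    average_precision = list(base = curve_base$average_precision,
                             boosted = curve_boosted$average_precision),
    precision_at_0.1 = list(base = precision_at_recall(curve_base, 0.1),
                            boosted = precision_at_recall(curve_boosted, 0.1)),
    pr_curves = list(base = curve_base$interp_precision,
                     boosted = curve_boosted$interp_precision))
  jsonlite::write_json(report, paths$evaluation, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(log_lines, paths$log)

  list(counts = report$counts,
       metrics = report$set_metrics,
       curves = list(base = curve_base, boosted = curve_boosted),
       ranked = ranked, config_hash = hash, paths = paths)
}
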