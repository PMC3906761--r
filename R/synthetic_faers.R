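#' Configuration for the synthetic spontaneous-report simulator
#'
#' The simulator emulates the data regime the signal-detection method
#' assumes: a spontaneous-report database where each report lists one or
#' more drugs (free-text strings, partly trade names, decorated with dosage
#' tokens) and coded adverse-event terms; a literature corpus whose
#' sentences co-mention drug--event pairs with probabilities depending on
#' the pair's true relationship (causal, treatment/indication, background
#' noise); a drug and side-effect lexicon; a gold standard (the planted
#' causal pairs); and an external score table.
#'
#' Event generation per report: each taken drug reports each of its
#' `k_causal` causal side effects with probability `p_causal_event`; each of
#' its `k_indic` indications is misreported as an event with probability
#' `p_indication_event` (confounding by indication); and a
#' `Poisson(lambda_noise)` number of uniformly random side effects is added.
#'
#' @param n_drugs,n_ses,n_reports vocabulary and database sizes.
#' @param k_causal causal side effects planted per drug.
#' @param k_indic indications planted per drug (disjoint from the causal
#'   set; these become the `TREAT` pairs).
#' @param p_causal_event probability a taken drug's causal side effect is
#'   reported in a given report.
#' @param p_indication_event probability a drug's indication is misreported
#'   as an event.
#' @param lambda_noise mean count of random noise events per report.
#' @param drugs_per_report mean number of drugs per report (>= 1; the count
#'   is `1 + Poisson(drugs_per_report - 1)`, capped at `n_drugs`).
#' @param p_lit_causal,p_lit_treat,p_lit_background probability that a
#'   causal / treatment / background pair receives a literature
#'   co-occurrence sentence.
#' @param trade_name_fraction fraction of drug mentions (in report strings
#'   and literature sentences) written as trade names.
#' @param drug_popularity `"zipf"` (default) draws report drugs with
#'   heavy-tailed popularity weights proportional to `1/rank`, the
#'   characteristic shape of report volumes in spontaneous-reporting
#'   databases, so co-report counts of causal pairs of rarely-reported drugs
#'   interleave with those of confounded pairs of heavily-reported drugs;
#'   `"uniform"` draws all drugs equally often (the closed forms in
#'   [expected_counts()] are exact only for this setting).
#' @param seed RNG seed (integer < 2^31 - 16; per-stage substreams are
#'   derived from it, so e.g. enlarging the report set does not perturb
#'   corpus generation).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_drugs = 200L, n_ses = 400L, n_reports = 50000L,
                       k_causal = 4L, k_indic = 2L,
                       p_causal_event = 0.3, p_indication_event = 0.15,
                       lambda_noise = 1.0, drugs_per_report = 1.4,
                       p_lit_causal = 0.4, p_lit_treat = 0.3,
                       p_lit_background = 0.002,
                       trade_name_fraction = 0.3,
                       drug_popularity = c("zipf", "uniform"), seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_ses = as.integer(n_ses),
              n_reports = as.integer(n_reports), k_causal = as.integer(k_causal),
              k_indic = as.integer(k_indic), p_causal_event = p_causal_event,
              p_indication_event = p_indication_event, lambda_noise = lambda_noise,
              drugs_per_report = drugs_per_report, p_lit_causal = p_lit_causal,
              p_lit_treat = p_lit_treat, p_lit_background = p_lit_background,
              trade_name_fraction = trade_name_fraction,
              drug_popularity = match.arg(drug_popularity),
              seed = suppressWarnings(as.integer(seed)))
  probs <- c(cfg$p_causal_event, cfg$p_indication_event, cfg$p_lit_causal,
             cfg$p_lit_treat, cfg$p_lit_background, cfg$trade_name_fraction)
  if (any(probs < 0 | probs > 1)) pb_validation_error("probabilities must be in [0, 1]")
  if (any(c(cfg$n_drugs, cfg$n_ses, cfg$n_reports) <= 0L)) {
    pb_validation_error("n_drugs, n_ses, n_reports must be positive")
  }
  if (cfg$k_causal < 0L || cfg$k_indic < 0L ||
      cfg$k_causal + cfg$k_indic > cfg$n_ses) {
    pb_validation_error("need 0 <= k_causal + k_indic <= n_ses")
  }
  if (cfg$lambda_noise < 0) pb_validation_error("lambda_noise must be >= 0")
  if (cfg$drugs_per_report < 1) pb_validation_error("drugs_per_report must be >= 1")
  if (is.na(cfg$seed) || cfg$seed < 0L || cfg$seed > 2147483600L) {
    pb_validation_error("seed must be an integer in [0, 2^31 - 48]")
  }
  structure(cfg, class = "sim_config")
}

pb_set_stage_seed <- function(cfg, offset) {
  set.seed(cfg$seed + offset, kind = "Mersenne-Twister", sample.kind = "Rejection")
}

# pronounceable pseudo-names, unique, deterministic under the current RNG state
pb_make_names <- function(n, suffixes) {
  syl <- c("ba", "ce", "da", "fi", "go", "lu", "ma", "ni", "pra", "ro",
           "sa", "ti", "vo", "xa", "zu", "ke", "mi", "tha", "bre", "clo")
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    cand <- paste0(
      syl[sample.int(length(syl), 2 * k, replace = TRUE)[seq_len(k)]],
      syl[sample.int(length(syl), k, replace = TRUE)],
      suffixes[sample.int(length(suffixes), k, replace = TRUE)])
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

pb_sim_vocab <- function(cfg) {
  pb_set_stage_seed(cfg, 0L)
  generics <- pb_make_names(cfg$n_drugs, c("mab", "nib", "pril", "olol", "statin",
                                           "cin", "vir", "zole", "ine", "ide"))
  trades <- pb_make_names(2L * cfg$n_drugs, c("ex", "on", "il", "or", "ix", "ax"))
  trades <- setdiff(trades, generics)[seq_len(cfg$n_drugs)]
  adjectives <- c("acute", "chronic", "severe", "transient", "persistent",
                  "progressive", "recurrent", "mild", "fulminant", "refractory",
                  "intermittent", "late", "early", "atypical", "ischemic",
                  "hemorrhagic", "congestive", "obstructive", "paroxysmal", "diffuse")
  nouns <- c("cardiomyopathy", "arrhythmia", "hepatitis", "neuropathy", "dermatitis",
             "nephritis", "colitis", "pneumonitis", "anemia", "thrombocytopenia",
             "hypertension", "hypotension", "bradycardia", "tachycardia", "edema",
             "rash", "vomiting", "dizziness", "syncope", "fatigue", "myalgia",
             "headache", "insomnia", "pruritus", "alopecia")
  grid <- expand.grid(adj = adjectives, noun = nouns, stringsAsFactors = FALSE)
  if (nrow(grid) < cfg$n_ses) {
    pb_validation_error(paste0("n_ses too large for the term pools (max ", nrow(grid), ")"))
  }
  pick <- sample.int(nrow(grid), cfg$n_ses)
  ses <- paste(grid$adj[pick], grid$noun[pick])
  categories <- c("cardiac disorders", "vascular disorders",
                  "gastrointestinal disorders", "nervous system disorders",
                  "skin disorders", "blood disorders")
  anc <- stats::setNames(as.list(categories[sample.int(length(categories),
                                                       cfg$n_ses, replace = TRUE)]), ses)
  list(generics = generics, trades = trades, ses = ses, ancestors = anc)
}

pb_sim_truth <- function(cfg, vocab) {
  pb_set_stage_seed(cfg, 1L)
  k <- cfg$k_causal + cfg$k_indic
  assign_mat <- vapply(seq_len(cfg$n_drugs),
                       function(i) sample.int(cfg$n_ses, k),
                       integer(k))
  assign_mat <- matrix(assign_mat, nrow = k)
  causal <- assign_mat[seq_len(cfg$k_causal), , drop = FALSE]
  indic <- if (cfg$k_indic > 0L) {
    assign_mat[cfg$k_causal + seq_len(cfg$k_indic), , drop = FALSE]
  } else matrix(integer(0), nrow = 0, ncol = cfg$n_drugs)
  list(causal = causal, indic = indic)
}

pb_truth_pairs <- function(cfg, vocab, truth) {
  mk <- function(mat) {
    if (nrow(mat) == 0L) return(data.table(drug = character(0), se = character(0)))
    dt <- data.table(drug = vocab$generics[rep(seq_len(cfg$n_drugs), each = nrow(mat))],
                     se = vocab$ses[as.vector(mat)])
    setorder(dt, drug, se)
    unique(dt)
  }
  list(causal_pairs = mk(truth$causal), treat_pairs = mk(truth$indic))
}

pb_sim_reports <- function(cfg, vocab, truth) {
  pb_set_stage_seed(cfg, 2L)
  n <- cfg$n_reports
  m <- pmin(1L + stats::rpois(n, cfg$drugs_per_report - 1), cfg$n_drugs)
  w <- if (cfg$drug_popularity == "zipf") 1 / seq_len(cfg$n_drugs) else NULL
  drug_idx <- lapply(m, function(k) sample.int(cfg$n_drugs, k, prob = w))
  rd <- data.table(report = rep(seq_len(n), m),
                   drug = unlist(drug_idx, use.names = FALSE))

  planted_events <- function(mat, p) {
    kk <- nrow(mat)
    if (kk == 0L || p == 0) return(data.table(report = integer(0), se = integer(0)))
    long <- data.table(report = rep(rd$report, each = kk),
                       se = as.vector(mat[, rd$drug]))
    long[stats::rbinom(nrow(long), 1L, p) == 1L]
  }
  ev_causal <- planted_events(truth$causal, cfg$p_causal_event)
  ev_indic <- planted_events(truth$indic, cfg$p_indication_event)
  n_noise <- stats::rpois(n, cfg$lambda_noise)
  ev_noise <- data.table(report = rep(seq_len(n), n_noise),
                         se = sample.int(cfg$n_ses, sum(n_noise), replace = TRUE))
  ev <- rbindlist(list(ev_causal, ev_indic, ev_noise))
  setorder(ev, report, se)

  # free-text drug strings: trade names at trade_name_fraction, dosage noise
  use_trade <- stats::runif(nrow(rd)) < cfg$trade_name_fraction
  nm <- ifelse(use_trade, vocab$trades[rd$drug], vocab$generics[rd$drug])
  patterns <- c("%s", "%s", "%s 100 mg", "%s 50 mg", "%s 10 mg tab",
                "%s 200 mg capsule", "%s injection", "%s 100 mg zenlabs /zl",
                "%s solution 5 mg/ml")
  fmt <- patterns[sample.int(length(patterns), nrow(rd), replace = TRUE)]
  rd[, string := sprintf(fmt, nm)]

  ids <- sprintf("r%07d", seq_len(n))
  list(drug_rows = data.table(report_id = ids[rd$report], drug_string = rd$string),
       reac_rows = data.table(report_id = ids[ev$report],
                              event_term = vocab$ses[ev$se]))
}

pb_sim_corpus <- function(cfg, vocab, truth_pairs) {
  pb_set_stage_seed(cfg, 3L)
  templates <- list(
    causal = c("patients receiving %s developed %s during follow up",
               "%s induced %s in a consecutive case series",
               "we report %s associated %s after two treatment cycles"),
    treat = c("%s was effective in the treatment of %s",
              "a randomized trial of %s for %s showed benefit",
              "%s therapy improved outcomes in patients with %s"),
    background = c("%s exposure and %s were both recorded in the registry",
                   "the registry listed %s use and %s among older adults"))
  pick_pairs <- function(pairs, p) {
    if (nrow(pairs) == 0L || p == 0) return(pairs[0])
    pairs[stats::runif(nrow(pairs)) < p]
  }
  lit_causal <- pick_pairs(truth_pairs$causal_pairs, cfg$p_lit_causal)
  lit_treat <- pick_pairs(truth_pairs$treat_pairs, cfg$p_lit_treat)
  planted_keys <- pb_pair_key(
    c(truth_pairs$causal_pairs$drug, truth_pairs$treat_pairs$drug),
    c(truth_pairs$causal_pairs$se, truth_pairs$treat_pairs$se))
  n_grid <- cfg$n_drugs * cfg$n_ses - length(unique(planted_keys))
  n_bg <- stats::rbinom(1L, n_grid, cfg$p_lit_background)
  bg <- data.table(drug = character(0), se = character(0))
  if (n_bg > 0L) {
    cand <- data.table(drug = vocab$generics[sample.int(cfg$n_drugs, 4L * n_bg + 8L,
                                                        replace = TRUE)],
                       se = vocab$ses[sample.int(cfg$n_ses, 4L * n_bg + 8L,
                                                 replace = TRUE)])
    cand <- unique(cand[!pb_pair_key(drug, se) %in% planted_keys])
    bg <- utils::head(cand, n_bg)
  }
  render <- function(pairs, tset) {
    if (nrow(pairs) == 0L) return(character(0))
    fmt <- tset[sample.int(length(tset), nrow(pairs), replace = TRUE)]
    # a fraction of literature drug mentions use the trade name, which the
    # index must map back to the generic
    di <- match(pairs$drug, vocab$generics)
    use_trade <- stats::runif(nrow(pairs)) < cfg$trade_name_fraction
    nm <- ifelse(use_trade, vocab$trades[di], pairs$drug)
    sprintf(fmt, nm, pairs$se)
  }
  sentences <- c(render(lit_causal, templates$causal),
                 render(lit_treat, templates$treat),
                 render(bg, templates$background))
  # distractors, including token-boundary traps where the planted term
  # appears only inside longer words ("subacute rashes" for "acute rash")
  n_dis <- max(20L, ceiling(0.5 * length(sentences)))
  d_only <- sprintf("pharmacokinetics of %s were linear across doses",
                    vocab$generics[sample.int(cfg$n_drugs, n_dis, replace = TRUE)])
  s_only <- sprintf("%s resolved without intervention in most patients",
                    vocab$ses[sample.int(cfg$n_ses, n_dis, replace = TRUE)])
  trap_se <- vocab$ses[sample.int(cfg$n_ses, n_dis, replace = TRUE)]
  trap_words <- strsplit(trap_se, " ", fixed = TRUE)
  traps <- sprintf("sub%s %ses were excluded from the analysis with %s",
                   vapply(trap_words, `[`, character(1), 1L),
                   vapply(trap_words, function(w) w[length(w)], character(1)),
                   vocab$generics[sample.int(cfg$n_drugs, n_dis, replace = TRUE)])
  sentences <- c(sentences, d_only, s_only, traps)
  sentences <- sentences[sample.int(length(sentences))]
  # group into documents of 2-5 sentences; within-document adjacency creates
  # abstract-level-only evidence (drug and SE in different sentences)
  sizes <- integer(0)
  while (sum(sizes) < length(sentences)) {
    sizes <- c(sizes, sample(2:5, 1L))
  }
  doc_of <- rep(seq_along(sizes), sizes)[seq_along(sentences)]
  docs <- lapply(split(sentences, doc_of), function(s) s)
  structure(Map(function(i, s) literature_document(sprintf("d%05d", i), s),
                seq_along(docs), unname(docs)),
            class = "literature_corpus")
}

pb_sim_external <- function(cfg, vocab, truth_pairs) {
  pb_set_stage_seed(cfg, 4L)
  take <- function(pairs, p, mu) {
    keep <- pairs[stats::runif(nrow(pairs)) < p]
    keep[, score := if (.N) stats::rnorm(.N, mu, 1) else numeric(0)]
    keep
  }
  cp <- take(data.table::copy(truth_pairs$causal_pairs), 0.7, 3)
  tp <- take(data.table::copy(truth_pairs$treat_pairs), 0.5, 2)
  n_bg <- ceiling(0.02 * cfg$n_drugs * cfg$n_ses)
  bg <- unique(data.table(
    drug = vocab$generics[sample.int(cfg$n_drugs, n_bg, replace = TRUE)],
    se = vocab$ses[sample.int(cfg$n_ses, n_bg, replace = TRUE)]))
  bg[, score := stats::rnorm(.N, 0.5, 1)]
  out <- rbindlist(list(cp, tp, bg))
  out <- out[, list(score = max(score)), by = c("drug", "se")]
  setorder(out, drug, se)
  structure(out, class = c("external_scores", class(out)))
}

#' Simulate a complete synthetic input bundle
#'
#' Generates and writes every input the pipeline consumes: paired
#' drug/reaction report files (TSV dialect), a sentence-level literature
#' corpus, drug and side-effect lexicon files, a gold standard (the planted
#' causal pairs), and an external score table. Identical config and seed
#' give byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return list with `paths` (named file paths: `drug_file`, `reac_file`,
#'   `corpus`, `drug_lexicon`, `se_lexicon`, `gold`, `external_scores`),
#'   `truth` (list of data.tables `causal_pairs`, `treat_pairs` — disjoint),
#'   and `config`.
#' @export
simulate_faers <- function(cfg = sim_config(), outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  vocab <- pb_sim_vocab(cfg)
  truth <- pb_sim_truth(cfg, vocab)
  truth_pairs <- pb_truth_pairs(cfg, vocab, truth)
  rows <- pb_sim_reports(cfg, vocab, truth)
  corpus <- pb_sim_corpus(cfg, vocab, truth_pairs)
  ext <- pb_sim_external(cfg, vocab, truth_pairs)

  paths <- list(
    drug_file = file.path(outdir, "drug.tsv"),
    reac_file = file.path(outdir, "reac.tsv"),
    corpus = file.path(outdir, "corpus.tsv"),
    drug_lexicon = file.path(outdir, "drug_lexicon.tsv"),
    se_lexicon = file.path(outdir, "se_lexicon.tsv"),
    gold = file.path(outdir, "gold.tsv"),
    external_scores = file.path(outdir, "external_scores.tsv"))

  fwrite(rows$drug_rows, paths$drug_file, sep = "\t", quote = FALSE)
  fwrite(rows$reac_rows, paths$reac_file, sep = "\t", quote = FALSE)
  write_corpus(corpus, paths$corpus)
  dlex <- drug_lexicon(vocab$generics, stats::setNames(vocab$generics, vocab$trades))
  slex <- se_lexicon(vocab$ses, vocab$ancestors)
  write_lexicons(dlex, slex, paths$drug_lexicon, paths$se_lexicon)
  write_pairs(truth_pairs$causal_pairs, paths$gold)
  write_pairs(ext, paths$external_scores)

  list(paths = paths, truth = truth_pairs, config = cfg)
}

#' Closed-form expectations for the simulator
#'
#' Analytic summaries used in parameter-recovery tests. With drugs drawn
#' uniformly without replacement, the probability a given drug appears in a
#' report is `E[m]/n_drugs` exactly (by symmetry), where `m` is the capped
#' per-report drug count. The expected co-report count of a causal pair
#' through its causal channel is then
#' `n_reports * P(drug drawn) * p_causal_event` (noise and indication
#' channels add a small extra contribution not included here).
#'
#' For uniform drug popularity the inclusion probability is exact; for
#' Zipf popularity a first-order approximation `E[m] * w_d / sum(w)` is
#' returned per drug (adequate while `E[m]` is small relative to the
#' effective number of drugs).
#'
#' @param cfg a [sim_config()].
#' @return list with `e_drugs_per_report`, `p_drug_drawn` (scalar for
#'   uniform popularity, per-drug vector for Zipf), and `e_pair_causal` /
#'   `e_pair_treat`, the causal-/indication-channel expectations of the
#'   co-report count of a planted pair of that drug (same shape as
#'   `p_drug_drawn`).
#' @export
expected_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lam <- cfg$drugs_per_report - 1
  kmax <- max(cfg$n_drugs, ceiling(lam + 12 * sqrt(lam + 1)) + 10L)
  k <- 0:kmax
  e_m <- sum(stats::dpois(k, lam) * pmin(1 + k, cfg$n_drugs)) +
    (1 - stats::ppois(kmax, lam)) * cfg$n_drugs
  p_drug <- if (cfg$drug_popularity == "uniform") {
    e_m / cfg$n_drugs  # exact by symmetry
  } else {
    w <- 1 / seq_len(cfg$n_drugs)
    pmin(1, e_m * w / sum(w))
  }
  list(e_drugs_per_report = e_m,
       p_drug_drawn = p_drug,
       e_pair_causal = cfg$n_reports * p_drug * cfg$p_causal_event,
       e_pair_treat = cfg$n_reports * p_drug * cfg$p_indication_event)
}
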