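# Independent brute-force oracles used to cross-check the library path.
# They are deliberately written with different machinery (regex scans,
# per-report double loops, per-level max searches) than the implementation.

# --- naive token-boundary dictionary scan (no greedy matching machinery) ----
# returns the set of canonical names whose term occurs as a contiguous token
# subsequence of the string; `terms` named character: term -> canonical
oracle_dict_scan <- function(s, terms) {
  toks <- strsplit(tolower(gsub("[^[:alnum:]]+", " ", s)), " +")[[1]]
  toks <- toks[nzchar(toks)]
  hits <- character(0)
  for (term in names(terms)) {
    tt <- strsplit(tolower(term), " +")[[1]]
    k <- length(tt)
    if (k == 0 || k > length(toks)) next
    for (i in seq_len(length(toks) - k + 1)) {
      if (all(toks[i:(i + k - 1)] == tt)) { hits <- c(hits, terms[[term]]); break }
    }
  }
  unique(unname(hits))
}

# --- naive quadratic pair extraction over reports ---------------------------
# lexicons given as plain vectors; counting logic re-derived per report
oracle_extract <- function(reports, generics, trade_map, se_terms) {
  dict <- c(stats::setNames(generics, generics), trade_map)
  pair_n <- new.env(parent = emptyenv())
  drug_n <- new.env(parent = emptyenv())
  se_n <- new.env(parent = emptyenv())
  N <- 0L
  for (r in reports) {
    D <- unique(unlist(lapply(r$drug_strings, oracle_dict_scan, terms = dict)))
    S <- unique(tolower(trimws(r$event_terms)))
    S <- S[S %in% se_terms]
    if (length(D) == 0 || length(S) == 0) next
    N <- N + 1L
    bump <- function(env, key) assign(key, (get0(key, envir = env) %||% 0L) + 1L, envir = env)
    for (d in D) bump(drug_n, d)
    for (s in S) bump(se_n, s)
    for (d in D) for (s in S) bump(pair_n, paste(d, s, sep = "\t"))
  }
  env2dt <- function(env) {
    keys <- sort(ls(env))
    stats::setNames(vapply(keys, get, numeric(1), envir = env), keys)
  }
  list(pair_n = env2dt(pair_n), drug_n = env2dt(drug_n), se_n = env2dt(se_n), N = N)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- brute-force 11-point interpolated precision ----------------------------
# direct per-level max search over all ranks
oracle_interp11 <- function(is_gold, denom = sum(is_gold)) {
  n <- length(is_gold)
  tp <- cumsum(is_gold)
  prec <- tp / seq_len(n)
  rec <- tp / denom
  vapply(seq(0, 1, by = 0.1), function(lv) {
    ok <- rec >= lv - 1e-12
    if (!any(ok)) 0 else max(prec[ok])
  }, numeric(1))
}

# --- brute-force literature co-occurrence counts ----------------------------
# double loop over pairs x sentences; drug trade names resolved before search
oracle_evidence <- function(corpus, pairs, trade_map = character(0)) {
  res <- data.frame(drug = pairs$drug, se = pairs$se,
                    sentence = 0L, abstract = 0L)
  rev_map <- split(names(trade_map), unname(trade_map))
  for (i in seq_len(nrow(pairs))) {
    drug_forms <- c(pairs$drug[i], rev_map[[pairs$drug[i]]])
    se <- pairs$se[i]
    for (doc in corpus) {
      in_doc_drug <- FALSE; in_doc_se <- FALSE
      for (s in doc$sentences) {
        has_d <- any(vapply(drug_forms, function(f)
          length(oracle_dict_scan(s, stats::setNames(f, f))) > 0, logical(1)))
        has_s <- length(oracle_dict_scan(s, stats::setNames(se, se))) > 0
        if (has_d && has_s) res$sentence[i] <- res$sentence[i] + 1L
        in_doc_drug <- in_doc_drug || has_d
        in_doc_se <- in_doc_se || has_s
      }
      if (in_doc_drug && in_doc_se) res$abstract[i] <- res$abstract[i] + 1L
    }
  }
  res
}

# --- shared tiny fixtures ---------------------------------------------------
tiny_drug_lex <- function() {
  drug_lexicon(c("cetuximab", "warfarin", "aspirin", "irinotecan", "baclofen"),
               c(erbitux = "cetuximab", coumadin = "warfarin"))
}

tiny_se_lex <- function() {
  se_lexicon(c("nausea", "myocardial infarction", "decreased activity",
               "colorectal cancer", "rash", "dizziness"),
             list("myocardial infarction" = "cardiac disorders",
                  "rash" = "skin disorders"))
}

# deterministic random contingency tables (cells 0..n) for property tests
random_tables <- function(n_tables, max_cell = 60, seed = 404) {
  set.seed(seed)
  data.frame(a = sample(0:max_cell, n_tables, TRUE),
             b = sample(0:max_cell, n_tables, TRUE),
             c = sample(0:max_cell, n_tables, TRUE),
             d = sample(0:max_cell, n_tables, TRUE))
}
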