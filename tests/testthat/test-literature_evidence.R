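mk_corpus <- function(...) {
  docs <- list(...)
  structure(Map(function(i, s) literature_document(paste0("d", i), s),
                seq_along(docs), docs),
            class = "literature_corpus")
}

test_that("index postings are token-boundary occurrences per sentence", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  corpus <- mk_corpus(
    c("baclofen was given", "later baclofen again", "the toxicity was mild"),
    c("no drug here"))
  idx <- build_index(corpus, dlex, slex)
  bp <- idx$drug_postings[idx$drug_postings$term == "baclofen", ]
  expect_identical(nrow(bp), 2L)
  expect_identical(bp$sentence_index, c(0L, 1L))
  # "ici" never indexed from inside "toxicity"; absent terms have no postings
  expect_false("irinotecan" %in% idx$drug_postings$term)
  expect_identical(nrow(idx$se_postings), 0L)
})

test_that("sentence-level requires same-sentence co-occurrence; abstract-level same document", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  pairs <- data.frame(drug = "baclofen", se = "decreased activity")
  same <- mk_corpus(c("although baclofen decreased activity during a 30 min period"))
  ev <- evidence_for(pairs, build_index(same, dlex, slex))
  expect_identical(ev$sentence$count, 1L)
  expect_identical(ev$abstract$count, 1L)

  split_doc <- mk_corpus(c("baclofen was administered", "decreased activity was noted"))
  ev2 <- evidence_for(pairs, build_index(split_doc, dlex, slex))
  expect_identical(nrow(ev2$sentence), 0L)
  expect_identical(ev2$abstract$count, 1L)
  expect_identical(nrow(evidence_set(ev2, "sentence")), 0L)
  expect_identical(nrow(evidence_set(ev2, "abstract")), 1L)
})

test_that("trade names in sentences resolve to generics before lookup", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  corpus <- mk_corpus(c("erbitux caused rash in two patients"))
  ev <- evidence_for(data.frame(drug = "cetuximab", se = "rash"),
                     build_index(corpus, dlex, slex))
  expect_identical(ev$sentence$count, 1L)
})

test_that("sentence evidence set is always a subset of the abstract set", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  set.seed(44)
  drugs <- dlex$generics; ses <- slex$terms
  for (trial in 1:5) {
    docs <- lapply(1:8, function(i) {
      n <- sample(1:4, 1)
      vapply(seq_len(n), function(j) {
        paste(sample(c(sample(drugs, 1), sample(ses, 1), "filler", "words"),
                     sample(2:4, 1)), collapse = " ")
      }, character(1))
    })
    corpus <- do.call(mk_corpus, docs)
    pairs <- expand.grid(drug = drugs, se = ses, stringsAsFactors = FALSE)
    ev <- evidence_for(pairs, build_index(corpus, dlex, slex))
    s <- evidence_set(ev, "sentence"); a <- evidence_set(ev, "abstract")
    skey <- paste(s$drug, s$se); akey <- paste(a$drug, a$se)
    expect_true(all(skey %in% akey))
    # and each pair's doc-level count bounds its sentence-contributing docs
    m <- merge(ev$sentence, ev$abstract, by = c("drug", "se"))
    expect_true(all(m$count.y >= 1 | nrow(m) == 0))
  }
})

test_that("counts equal a brute-force double loop on a 20-document corpus", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  set.seed(123)
  drugs <- c(dlex$generics, names(dlex$trade_to_generic))
  docs <- lapply(1:20, function(i) {
    vapply(seq_len(sample(1:4, 1)), function(j) {
      toks <- c(sample(drugs, sample(0:2, 1)), sample(slex$terms, sample(0:2, 1)),
                sample(c("the", "study", "of", "toxicity"), 2))
      paste(sample(toks), collapse = " ")
    }, character(1))
  })
  corpus <- do.call(mk_corpus, docs)
  pairs <- expand.grid(drug = dlex$generics, se = slex$terms, stringsAsFactors = FALSE)
  ev <- evidence_for(pairs, build_index(corpus, dlex, slex))
  oc <- oracle_evidence(corpus, pairs, dlex$trade_to_generic)
  want_s <- oc[oc$sentence > 0, c("drug", "se", "sentence")]
  got_s <- as.data.frame(ev$sentence)
  expect_equal(got_s[order(got_s$drug, got_s$se), ],
               stats::setNames(want_s[order(want_s$drug, want_s$se), ],
                               c("drug", "se", "count")),
               ignore_attr = TRUE)
  want_a <- oc[oc$abstract > 0, c("drug", "se", "abstract")]
  got_a <- as.data.frame(ev$abstract)
  expect_equal(got_a[order(got_a$drug, got_a$se), ],
               stats::setNames(want_a[order(want_a$drug, want_a$se), ],
                               c("drug", "se", "count")),
               ignore_attr = TRUE)
})

test_that("counts are additive over disjoint corpus partitions", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  part1 <- mk_corpus(c("aspirin then nausea", "aspirin alone"))
  part2 <- structure(list(literature_document("x1", "aspirin with nausea and rash")),
                     class = "literature_corpus")
  whole <- structure(c(unclass(part1), unclass(part2)), class = "literature_corpus")
  pairs <- data.frame(drug = "aspirin", se = "nausea")
  cnt <- function(corp) {
    e <- evidence_for(pairs, build_index(corp, dlex, slex))
    c(s = sum(e$sentence$count), a = sum(e$abstract$count))
  }
  expect_equal(cnt(whole), cnt(part1) + cnt(part2))
})

test_that("planted co-occurrences are recovered exactly and empty corpora give empty sets", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  planted <- data.frame(drug = c("aspirin", "warfarin", "baclofen", "irinotecan", "cetuximab"),
                        se = c("nausea", "rash", "dizziness", "colorectal cancer", "rash"))
  docs <- lapply(seq_len(nrow(planted)), function(i) {
    sprintf("%s was followed by %s", planted$drug[i], planted$se[i])
  })
  corpus <- do.call(mk_corpus, docs)
  allpairs <- expand.grid(drug = dlex$generics, se = slex$terms, stringsAsFactors = FALSE)
  ev <- evidence_for(allpairs, build_index(corpus, dlex, slex))
  got <- evidence_set(ev, "sentence")
  expect_equal(as.data.frame(got[order(got$drug), ]),
               planted[order(planted$drug), ], ignore_attr = TRUE)

  empty <- structure(list(), class = "literature_corpus")
  ev0 <- evidence_for(allpairs, build_index(empty, dlex, slex))
  expect_identical(nrow(evidence_set(ev0, "abstract")), 0L)
})

test_that("a sentence filter hook restricts sentence-level evidence", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  corpus <- mk_corpus(c("baclofen decreased activity during the test"),
                      c("baclofen caused decreased activity"))
  pairs <- data.frame(drug = "baclofen", se = "decreased activity")
  idx <- build_index(corpus, dlex, slex)
  ev_all <- evidence_for(pairs, idx)
  expect_identical(ev_all$sentence$count, 2L)
  drop_bare <- function(text, drug, se) grepl("caused", text, fixed = TRUE)
  ev_f <- evidence_for(pairs, idx, sentence_filter = drop_bare)
  expect_identical(ev_f$sentence$count, 1L)
})
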