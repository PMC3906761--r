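test_that("normalization lowercases, collapses whitespace, strips punctuation, and is idempotent", {
  expect_identical(pb_normalize("  NAUSEA "), "nausea")
  expect_identical(pb_normalize("-Warfarin   SODIUM-"), "warfarin sodium")
  expect_identical(pb_normalize(character(0)), character(0))
  set.seed(11)
  raw <- replicate(50, paste(sample(c("A", "b", " ", "-", ".", "x", "1"), 12, TRUE),
                             collapse = ""))
  expect_identical(pb_normalize(pb_normalize(raw)), pb_normalize(raw))
})

write_tsv <- function(lines, path) writeLines(lines, path)

test_that("read_reports joins drug and reaction rows by report ID with outer-merge semantics", {
  d <- withr::local_tempfile(fileext = ".tsv")
  r <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(c("report_id\tdrug_string", "r1\taspirin", "r1\twarfarin", "\torphan"), d)
  write_tsv(c("report_id\tevent_term", "r1\tnausea", "r2\trash"), r)
  reports <- read_reports(d, r, "tsv")
  expect_length(reports, 2L)
  rec1 <- reports[[which(vapply(reports, `[[`, "", "report_id") == "r1")]]
  expect_identical(rec1$drug_strings, c("aspirin", "warfarin"))
  expect_identical(rec1$event_terms, "nausea")
  rec2 <- reports[[which(vapply(reports, `[[`, "", "report_id") == "r2")]]
  expect_identical(rec2$drug_strings, character(0))  # REAC-only report
  expect_identical(attr(reports, "n_skipped_drug_rows"), 1L)
})

test_that("read_reports handles the dollar-delimited dialect and rejects malformed headers", {
  d <- withr::local_tempfile(fileext = ".txt")
  r <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ISR$DRUG_SEQ$DRUGNAME", "100$1$erbitux 100 mg", "100$2$coumadin"), d)
  writeLines(c("ISR$PT", "100$nausea"), r)
  reports <- read_reports(d, r, "faers_dollar")
  expect_length(reports, 1L)
  expect_identical(reports[[1]]$drug_strings, c("erbitux 100 mg", "coumadin"))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("justonecolumn", "100"), bad)
  err <- tryCatch(read_reports(bad, r, "faers_dollar"), condition = identity)
  expect_s3_class(err, "pb_format_error")
  expect_match(conditionMessage(err), basename(bad), fixed = TRUE)
  expect_identical(pb_exit_code(err), 3L)
  expect_error(read_reports(d, r, "excel"), class = "pb_config_error")
})

test_that("read_reports is invariant to input row order up to per-report list order", {
  d1 <- withr::local_tempfile(); r1 <- withr::local_tempfile()
  d2 <- withr::local_tempfile(); r2 <- withr::local_tempfile()
  rows <- c("r2\tb", "r1\ta", "r3\tc")
  write_tsv(c("report_id\tdrug_string", rows), d1)
  write_tsv(c("report_id\tdrug_string", rev(rows)), d2)
  write_tsv(c("report_id\tevent_term", "r1\tx", "r2\ty"), r1)
  write_tsv(c("report_id\tevent_term", "r2\ty", "r1\tx"), r2)
  a <- read_reports(d1, r1, "tsv"); b <- read_reports(d2, r2, "tsv")
  key <- function(rs) lapply(rs, function(x) list(x$report_id,
                                                  sort(x$drug_strings), sort(x$event_terms)))
  expect_identical(key(a), key(b))
})

test_that("lexicon reading maps trade names, resolves conflicts deterministically, validates targets", {
  dl <- withr::local_tempfile(); sl <- withr::local_tempfile()
  write_tsv(c("name\tgeneric\tkind",
              "cetuximab\tcetuximab\tgeneric",
              "aciclovir\taciclovir\tgeneric",
              "Erbitux\tcetuximab\ttrade",
              "drugx\tcetuximab\ttrade",
              "drugx\taciclovir\ttrade"), dl)
  write_tsv(c("term\tancestors",
              "myocardial infarction\tcardiac disorders",
              "nausea\t"), sl)
  expect_warning(lex <- read_lexicons(dl, sl), "lexicographically")
  expect_identical(lex$drug$trade_to_generic[["erbitux"]], "cetuximab")
  expect_identical(lex$drug$trade_to_generic[["drugx"]], "aciclovir")  # smallest generic
  expect_identical(lex$se$ancestors[["nausea"]], character(0))
  expect_setequal(se_subset(lex$se, "cardiac disorders"), "myocardial infarction")

  bad <- withr::local_tempfile()
  write_tsv(c("name\tgeneric\tkind", "zzz\tnotthere\ttrade"), bad)
  expect_error(read_lexicons(bad, sl), class = "pb_validation_error")
})

test_that("lexicon write/read round-trips", {
  dl <- withr::local_tempfile(); sl <- withr::local_tempfile()
  write_lexicons(tiny_drug_lex(), tiny_se_lex(), dl, sl)
  back <- read_lexicons(dl, sl)
  expect_identical(back$drug, tiny_drug_lex())
  expect_identical(back$se, tiny_se_lex())
})

test_that("corpus reading keeps sentence order, tolerates interleaving, rejects index gaps", {
  f <- withr::local_tempfile()
  write_tsv(c("doc_id\tsentence_index\ttext",
              "d1\t0\tfirst of d1", "d2\t0\tfirst of d2",
              "d1\t1\tsecond of d1"), f)
  corpus <- read_corpus(f)
  expect_length(corpus, 2L)
  expect_identical(corpus[[1]]$doc_id, "d1")
  expect_identical(corpus[[1]]$sentences, c("first of d1", "second of d1"))

  empty <- withr::local_tempfile()
  write_tsv("doc_id\tsentence_index\ttext", empty)
  expect_length(read_corpus(empty), 0L)

  gap <- withr::local_tempfile()
  write_tsv(c("doc_id\tsentence_index\ttext", "d1\t0\ta", "d1\t2\tb"), gap)
  expect_error(read_corpus(gap), class = "pb_format_error")

  rt <- withr::local_tempfile()
  write_corpus(corpus, rt)
  expect_identical(read_corpus(rt), corpus)
})

test_that("pair lists deduplicate, parse numeric scores, and round-trip through writers", {
  f <- withr::local_tempfile()
  write_tsv(c("drug\tse", "a\tx", "a\tx", "b\ty", "c\tz"), f)
  g <- read_gold(f)
  expect_identical(nrow(g), 3L)

  s <- withr::local_tempfile()
  write_tsv(c("drug\tse\tscore", "a\tx\t1e3"), s)
  ext <- read_external_scores(s)
  expect_identical(ext$score, 1000)

  bad <- withr::local_tempfile()
  write_tsv(c("drug\tse\tscore", "a\tx\tNaNopes"), bad)
  err <- tryCatch(read_external_scores(bad), condition = identity)
  expect_s3_class(err, "pb_format_error")

  out <- withr::local_tempfile()
  write_pairs(g, out)
  expect_equal(as.data.frame(read_pairs(out)), as.data.frame(g))
  # byte-stable: writing the read-back file reproduces it exactly
  out2 <- withr::local_tempfile()
  write_pairs(read_pairs(out), out2)
  expect_identical(readLines(out), readLines(out2))
})
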