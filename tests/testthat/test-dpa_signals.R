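# independent recomputation of each statistic straight from its formula,
# kept separate from the vectorized implementation
oracle_stats <- function(a, b, c, d) {
  N <- a + b + c + d
  list(prr = (a / (a + b)) / (c / (c + d)),
       ror = (a * d) / (b * c),
       rrr = a * N / ((a + b) * (a + c)),
       phi = (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d)),
       ic = log2(a * N / ((a + b) * (a + c))))
}

test_that("closed-form values match an independent evaluation of the formulas", {
  cases <- list(c(10, 90, 10, 890), c(20, 80, 10, 890), c(17, 41, 8, 934))
  for (cc in cases) {
    t <- contingency_table(cc[1], cc[2], cc[3], cc[4])
    o <- oracle_stats(cc[1], cc[2], cc[3], cc[4])
    expect_equal(as.numeric(prr(t)), o$prr)
    expect_equal(as.numeric(ror(t)), o$ror)
    expect_equal(rrr(t), o$rrr)
    expect_equal(phi_corr(t), o$phi)
    expect_equal(ic(t), o$ic)
  }
  # spot values
  expect_equal(as.numeric(prr(contingency_table(10, 90, 10, 890))), 9)
  expect_equal(as.numeric(prr(contingency_table(20, 80, 10, 890))), 18)
  expect_equal(as.numeric(ror(contingency_table(20, 80, 10, 890))), 22.25)
  expect_equal(rrr(contingency_table(10, 90, 10, 890)), 5)
  expect_equal(phi_corr(contingency_table(20, 80, 10, 890)), 0.3322, tolerance = 1e-3)
  expect_equal(ic(contingency_table(10, 90, 10, 890)), log2(5))
  expect_equal(freq(contingency_table(17306, 1, 1, 1)), 17306)
  expect_equal(freq(contingency_table(0, 5, 5, 5)), 0)
})

test_that("independence nulls: PRR = ROR = RRR = 1, phi = 0, raw IC = 0", {
  set.seed(12)
  for (i in 1:20) {
    a <- sample(1:30, 1); r1 <- sample(1:9, 1); r2 <- sample(1:9, 1)
    t <- contingency_table(a, a * r1, a * r2, a * r1 * r2)  # ad = bc
    expect_equal(as.numeric(prr(t)), 1)
    expect_equal(as.numeric(ror(t)), 1)
    expect_equal(rrr(t), 1)
    expect_equal(phi_corr(t), 0)
    expect_equal(ic(t), 0)
  }
})

test_that("zero cells are corrected for PRR/ROR and flagged; undefined markers are NA", {
  t0 <- contingency_table(3, 0, 2, 10)
  expect_true(attr(prr(t0), "corrected"))
  expect_true(attr(ror(t0), "corrected"))
  expect_true(is.finite(as.numeric(ror(t0))))
  expect_false(attr(prr(contingency_table(3, 4, 2, 10)), "corrected"))

  empty_row <- contingency_table(0, 0, 5, 10)
  expect_true(is.na(as.numeric(prr(empty_row))))
  expect_true(is.na(phi_corr(empty_row)))          # zero marginal
  expect_equal(phi_corr(contingency_table(4, 0, 0, 7)), 1)  # perfect association
  expect_equal(rrr(contingency_table(0, 10, 10, 80)), 0)
  expect_true(is.na(ic(contingency_table(0, 10, 10, 80), "raw")))
  shr <- ic(contingency_table(0, 10, 10, 80), "shrunk")
  E <- 10 * 10 / 100
  expect_equal(shr, log2(0.5 / (E + 0.5)))
  expect_lt(shr, 0)
})

test_that("random-table properties: ROR >= PRR >= 1 together, phi in [-1,1], IC = log2(RRR)", {
  tabs <- random_tables(300)
  for (i in seq_len(nrow(tabs))) {
    t <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    p <- as.numeric(prr(t)); r <- as.numeric(ror(t))
    if (!is.na(p) && !attr(prr(t), "corrected") && p >= 1) {
      expect_gte(r + 1e-12, p)
    }
    ph <- phi_corr(t)
    if (!is.na(ph)) expect_true(ph >= -1 - 1e-12 && ph <= 1 + 1e-12)
    icv <- ic(t)
    if (!is.na(icv)) expect_equal(icv, log2(rrr(t)))
  }
})

test_that("DPA measures are scale-invariant except shrunk IC", {
  tabs <- random_tables(40, max_cell = 25, seed = 90)
  tabs <- tabs + 1  # strictly positive cells so no correction path
  for (i in seq_len(nrow(tabs))) {
    t1 <- contingency_table(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    k <- sample(2:6, 1)
    t2 <- contingency_table(k * tabs$a[i], k * tabs$b[i], k * tabs$c[i], k * tabs$d[i])
    expect_equal(as.numeric(prr(t1)), as.numeric(prr(t2)))
    expect_equal(as.numeric(ror(t1)), as.numeric(ror(t2)))
    expect_equal(rrr(t1), rrr(t2))
    expect_equal(phi_corr(t1), phi_corr(t2))
    expect_equal(ic(t1), ic(t2))
  }
  # the shrinkage term breaks scale invariance by design
  t1 <- contingency_table(2, 8, 3, 87); t2 <- contingency_table(20, 80, 30, 870)
  expect_false(isTRUE(all.equal(ic(t1, "shrunk"), ic(t2, "shrunk"))))
})

test_that("score_all equals per-pair application of the unit operations", {
  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  set.seed(31)
  reports <- lapply(1:50, function(i) {
    report_record(paste0("r", i),
                  sample(c("aspirin", "warfarin", "coumadin", "baclofen"), sample(1:2, 1)),
                  sample(c("nausea", "rash", "dizziness"), sample(1:2, 1)))
  })
  pc <- extract_pairs(reports, dlex, slex)
  for (m in c("freq", "prr", "rrr", "ror", "phi", "ic")) {
    sc <- score_all(pc, m)
    for (i in seq_len(nrow(sc))) {
      t <- contingency(pc, sc$drug[i], sc$se[i])
      want <- switch(m, freq = freq(t), prr = as.numeric(prr(t)),
                     rrr = rrr(t), ror = as.numeric(ror(t)),
                     phi = phi_corr(t), ic = ic(t))
      expect_equal(sc$value[i], want)
    }
  }
})

test_that("external scores rank present pairs by table value and mark absent pairs", {
  f <- withr::local_tempfile()
  writeLines(c("drug\tse\tscore", "aspirin\tnausea\t2.5", "warfarin\trash\t-1"), f)
  ext <- read_external_scores(f)
  expect_equal(external_signal("aspirin", "nausea", ext), 2.5)
  expect_true(is.na(external_signal("aspirin", "rash", ext)))

  dlex <- tiny_drug_lex(); slex <- tiny_se_lex()
  reports <- list(report_record("r1", c("aspirin", "warfarin"), c("nausea", "rash")))
  pc <- extract_pairs(reports, dlex, slex)
  sc <- score_all(pc, "external", external = ext)
  expect_equal(sc$value[sc$drug == "aspirin" & sc$se == "nausea"], 2.5)
  expect_true(is.na(sc$value[sc$drug == "aspirin" & sc$se == "rash"]))
  expect_error(score_all(pc, "external"), class = "pb_validation_error")
  expect_error(score_all(pc, "nonsense"), class = "pb_config_error")
})
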