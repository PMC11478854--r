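# Interval-weighted score: tf_interval * (1/df_corpus) * (D_corpus/D_interval)

test_that("the interval-weighted score matches direct arithmetic on a toy corpus", {
  # 4 docs in 2 intervals; term "x" occurs 2x among the 10 tokens of 2019
  # (tf = 0.2) and sits in 2 of 4 documents (df = 0.5); D ratio = 4/2
  docs <- list(
    pdoc("1", list(c("x", "a", "b", "c", "x")), year = 2019L),
    pdoc("2", list(c("a", "b", "c", "d", "e")), year = 2019L),
    pdoc("3", list(c("x", "a", "b")), year = 2020L),
    pdoc("4", list(c("c", "d", "f")), year = 2020L)
  )
  tab <- build_term_score_table(docs)
  expect_equal(interval_weighted_tfidf("x", "2019", tab), 0.2 * 2 * 2)
  # "f" occurs only in 2020, so it is absent from the 2019 interval -> 0
  expect_identical(interval_weighted_tfidf("f", "2019", tab), 0)
  # absent from the corpus entirely -> 0 (df guard)
  expect_identical(interval_weighted_tfidf("zzz", "2019", tab), 0)
  expect_error(interval_weighted_tfidf("x", "1999", tab), "unknown interval")
})

test_that("corpus-wide score is the single-interval reduction", {
  # term count 3 of 20 corpus tokens, df = 0.5 -> 0.15 * 2 = 0.3
  docs <- list(
    pdoc("1", list(c("y", "y", "y", rep("a", 7))), year = 2020L),
    pdoc("2", list(rep(c("b", "c"), 5)), year = 2020L)
  )
  tab <- build_term_score_table(docs)
  expect_equal(corpus_tfidf("y", tab), 0.15 * 2)
  # single whole-corpus interval equals corpus-wide, exactly, for every term
  part <- interval_partition(docs, breaks = list(all = 2018:2022))
  tab1 <- build_term_score_table(docs, part)
  for (tm in tab1$terms) {
    expect_identical(interval_weighted_tfidf(tm, "all", tab1),
                     corpus_tfidf(tm, tab1))
  }
  # single-doc corpus where the term is every token -> score 1
  solo <- list(pdoc("1", list(c("q", "q")), year = 2020L))
  expect_equal(corpus_tfidf("q", build_term_score_table(solo)), 1)
})

test_that("random toy corpora agree with an independent brute-force recount", {
  set.seed(42)
  for (rep in 1:20) {
    docs <- random_toy_docs(sample(2:10, 1))
    years <- vapply(docs, `[[`, integer(1), "year")
    tab <- build_term_score_table(docs)
    for (tm in tab$terms) {
      for (lab in names(tab$interval_token_totals)) {
        expect_equal(
          interval_weighted_tfidf(tm, lab, tab),
          brute_force_tfidf(docs, tm, lab, years),
          tolerance = 1e-12
        )
      }
      # zero law: score 0 iff the interval count is 0
      for (lab in names(tab$interval_token_totals)) {
        cnt <- tab$interval_counts[tm, lab]
        sc <- interval_weighted_tfidf(tm, lab, tab)
        expect_identical(sc == 0, cnt == 0L)
      }
    }
  }
})

test_that("duplicating every document leaves all scores unchanged", {
  set.seed(7)
  docs <- random_toy_docs(5)
  dup <- c(docs, lapply(docs, function(d) {
    d$doc_id <- paste0(d$doc_id, "_copy")
    d
  }))
  tab <- build_term_score_table(docs)
  tab2 <- build_term_score_table(dup)
  for (tm in tab$terms) {
    expect_equal(corpus_tfidf(tm, tab2), corpus_tfidf(tm, tab))
    for (lab in names(tab$interval_token_totals)) {
      expect_equal(interval_weighted_tfidf(tm, lab, tab2),
                   interval_weighted_tfidf(tm, lab, tab))
    }
  }
})

test_that("undated documents count corpus-wide but join no interval", {
  docs <- list(
    pdoc("1", list(c("x", "a")), year = 2020L),
    pdoc("2", list(c("x", "b")), year = NA_integer_)
  )
  tab <- build_term_score_table(docs)
  expect_identical(names(tab$interval_token_totals), "2020")
  expect_identical(tab$partition$D_corpus, 1L)   # only dated docs
  expect_identical(tab$n_docs, 2L)               # both score corpus-wide
  expect_equal(corpus_tfidf("x", tab), 0.5 * 1)  # tf 2/4, df 2/2
})

test_that("ranking sorts by score with lexicographic tie-break and truncates", {
  docs <- list(pdoc("1", list(c("bmab", "amab", "zmab", "zmab", "other")),
                    year = 2020L))
  lex <- term_lexicon(data.frame(stem = "mab", position = "suffix"),
                      suffix_rules = "osis", dictionary = "other",
                      min_token_length = 4L)
  cls <- classify_corpus_terms(docs, lex)
  tab <- build_term_score_table(docs)
  r <- rank_terms(tab, cls, "drug_compound")
  expect_identical(r$term, c("zmab", "amab", "bmab"))  # tie a<b
  expect_identical(nrow(rank_terms(tab, cls, "drug_compound", top_k = 2)), 2L)
  expect_identical(nrow(rank_terms(tab, cls, "clinical_feature")), 0L)
})

test_that("score export carries one column per interval", {
  docs <- list(
    pdoc("1", list(c("azumab", "thrombosis", "filler")), year = 2019L),
    pdoc("2", list(c("azumab", "filler", "filler")), year = 2020L)
  )
  lex <- toy_lexicon()
  cls <- classify_corpus_terms(docs, lex)
  tab <- build_term_score_table(docs)
  out <- export_scores(tab, cls)
  expect_setequal(out$term, c("azumab", "thrombosis"))
  expect_true(all(c("term", "category", "corpus_score", "2019", "2020") %in%
                    names(out)))
})
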