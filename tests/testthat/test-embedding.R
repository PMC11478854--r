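small_config <- function(seed = 1L, ...) {
  embedding_config(dim = 25L, window = 4L, min_count = 2L, epochs = 3L,
                   seed = seed, ...)
}

repeat_sentences <- function(sentences, times) {
  rep(sentences, times)
}

test_that("training text merges corpora in deterministic order", {
  q <- list(pdoc("1", list(c("a", "b"), c("c", "d"))),
            pdoc("2", list(c("e", "f"))))
  a <- list(pdoc("3", list(c("g", "h"))))
  s <- build_training_text(q, a)
  expect_length(s, 4)
  expect_identical(s[[1]], c("a", "b"))
  expect_identical(s[[4]], c("g", "h"))
  expect_identical(s, build_training_text(q, a))
  expect_length(build_training_text(list(), list()), 0)
})

test_that("vocabulary respects min_count and training is seed-reproducible", {
  sentences <- repeat_sentences(list(c("alpha", "beta", "gamma"),
                                     c("alpha", "beta", "delta")), 3)
  sentences <- c(sentences, list(c("rare", "alpha")))
  sp <- train_embeddings(sentences, small_config())
  expect_true(all(c("alpha", "beta") %in% embedding_vocabulary(sp)))
  expect_false("rare" %in% embedding_vocabulary(sp))   # below min_count

  sp2 <- train_embeddings(sentences, small_config())
  expect_identical(sp$vectors, sp2$vectors)            # bit-reproducible

  sp3 <- train_embeddings(sentences, small_config(seed = 99L))
  expect_false(identical(sp$vectors, sp3$vectors))

  expect_error(train_embeddings(list(), small_config()), "empty training")
})

test_that("cosine similarity is symmetric, bounded, and errors out of vocabulary", {
  sentences <- repeat_sentences(list(c("one", "two", "three", "four")), 5)
  sp <- train_embeddings(sentences, small_config())
  v <- embedding_vocabulary(sp)
  expect_equal(similarity(sp, v[1], v[1]), 1)
  for (a in v) for (b in v) {
    s1 <- similarity(sp, a, b)
    expect_lte(s1, 1 + 1e-12)
    expect_gte(s1, -1 - 1e-12)
    expect_equal(s1, similarity(sp, b, a), tolerance = 1e-12)
  }
  expect_error(similarity(sp, "one", "nonexistent"), "nonexistent")
})

test_that("association classification partitions the drug vocabulary", {
  sentences <- repeat_sentences(list(
    c("drugx", "disease", "ctx"), c("drugy", "ctx", "filler"),
    c("drugz", "other", "ctx")
  ), 4)
  sp <- train_embeddings(sentences, small_config())
  recs <- classify_associations(
    sp, drug_terms = c("drugx", "drugy", "drugz", "unseen"),
    query_corpus_vocab = c("drugx", "disease"),
    prediction_term = "disease"
  )
  # every drug in the vocabulary yields exactly one record; unseen is absent
  expect_setequal(recs$drug_term, c("drugx", "drugy", "drugz"))
  expect_identical(recs$class[recs$drug_term == "drugx"], "direct")
  expect_setequal(recs$drug_term[recs$class == "indirect"],
                  c("drugy", "drugz"))
  # direct + indirect counts always sum to the drug vocabulary size
  expect_identical(sum(recs$class == "direct") +
                     sum(recs$class == "indirect"), nrow(recs))
  # sorted by similarity descending within class
  ind <- recs$similarity[recs$class == "indirect"]
  expect_true(all(diff(ind) <= 0))
  expect_error(
    classify_associations(sp, "drugx", character(), "notaterm"),
    "notaterm"
  )
  empty <- classify_associations(sp, character(), character(), "disease")
  expect_identical(nrow(empty), 0L)
})

test_that("property labels attach by exact lemma match only", {
  recs <- data.frame(
    drug_term = c("apixaban", "warfarin", "novel"),
    similarity = c(0.5, 0.4, 0.3),
    class = c("indirect", "indirect", "direct"),
    label = NA_character_, stringsAsFactors = FALSE
  )
  out <- label_properties(recs, c(Apixaban = "anti-thrombotic",
                                  missingdrug = "pro-thrombotic"))
  expect_identical(out$label[out$drug_term == "apixaban"], "anti-thrombotic")
  expect_true(is.na(out$label[out$drug_term == "warfarin"]))
  counts <- attr(out, "label_counts")
  expect_identical(as.integer(counts["indirect", "anti-thrombotic"]), 1L)
  # empty property list labels nothing
  out2 <- label_properties(recs, stats::setNames(character(), character()))
  expect_true(all(is.na(out2$label)))
})

test_that("planted co-occurrence beats background similarity in most seeds", {
  lex <- toy_lexicon()
  wins <- 0L
  for (s in 1:5) {
    spec <- synthetic_spec(n_docs = 150, bridging_strength = 0.9, seed = s)
    g <- generate_corpus(spec, default_lexicon())
    docs <- normalize_corpus(g$corpus)
    sp <- train_embeddings(build_training_text(docs),
                           embedding_config(dim = 30L, window = 5L,
                                            min_count = 5L, seed = s))
    v <- embedding_vocabulary(sp)
    pt <- g$manifest$prediction_term
    bridged <- intersect(g$manifest$bridged_drugs, v)
    backg <- intersect(g$manifest$background_drugs, v)
    sims_b <- vapply(bridged, similarity, numeric(1), space = sp, b = pt)
    sims_g <- vapply(backg, similarity, numeric(1), space = sp, b = pt)
    if (mean(sims_b) > stats::median(sims_g)) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("word-vector text format round-trips", {
  sentences <- repeat_sentences(list(c("aa", "bb", "cc")), 4)
  sp <- train_embeddings(sentences, small_config())
  path <- withr::local_tempfile(fileext = ".vec")
  save_embeddings(sp, path)
  back <- load_embeddings(path)
  expect_identical(rownames(back$vectors), rownames(sp$vectors))
  expect_equal(back$vectors, sp$vectors, tolerance = 1e-15,
               ignore_attr = TRUE)
})
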