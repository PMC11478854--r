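test_that("drug classification needs a stem match plus dictionary absence", {
  lex <- toy_lexicon()
  expect_true(is_drug_compound("guanylate", lex))     # "guan-" prefix
  expect_true(is_drug_compound("caplacizumab", lex))  # "-mab" suffix
  expect_false(is_drug_compound("map", lex))          # short + dictionary word
  expect_false(is_drug_compound("guano", lex))       # stem match vetoed by dictionary
  expect_true(is_drug_compound("azumab", lex))
  expect_false(is_drug_compound("amab", lex))         # below the length floor of 5
})

test_that("infix stems match only strictly inside the token", {
  lex <- toy_lexicon()
  expect_true(is_drug_compound("prazosins", lex))   # "osin" strictly inside
  expect_false(is_drug_compound("osinprep", lex))   # at left boundary
  expect_false(is_drug_compound("macrosin", lex))   # at right boundary
})

test_that("clinical features match glossary suffixes", {
  lex <- toy_lexicon()
  expect_true(is_clinical_feature("thrombosis", lex))
  expect_true(is_clinical_feature("dyspnea", lex))
  expect_true(is_clinical_feature("hypoxemia", lex))
  expect_false(is_clinical_feature("basis", lex))
  expect_false(is_clinical_feature("osis", lex))     # bare suffix is no term
})

test_that("corpus classification partitions the vocabulary", {
  lex <- toy_lexicon()
  docs <- list(pdoc("1", list(c("riociguat", "thrombosis", "lungs"))))
  # note tokens arrive already normalized; "lungs" here is intentionally raw
  cls <- classify_corpus_terms(docs, lex)
  expect_setequal(cls$term, c("riociguat", "thrombosis", "lungs"))
  expect_identical(terms_of_category(cls, "drug_compound"), "riociguat")
  expect_identical(terms_of_category(cls, "clinical_feature"), "thrombosis")
  expect_identical(terms_of_category(cls, "other"), "lungs")

  # partition: disjoint categories covering every distinct token
  expect_identical(anyDuplicated(cls$term), 0L)
  expect_true(all(cls$category %in%
                    c("drug_compound", "clinical_feature", "other")))

  expect_identical(nrow(classify_corpus_terms(list(), lex)), 0L)
})

test_that("drug takes precedence on a double match, configurably", {
  lex <- toy_lexicon()
  # "guanosis": guan- prefix (drug) and -osis suffix (feature)
  docs <- list(pdoc("1", list("guanosis")))
  expect_identical(classify_corpus_terms(docs, lex)$category, "drug_compound")

  lex2 <- term_lexicon(lex$stem_rules, lex$suffix_rules,
                       dictionary = lex$dictionary_words,
                       precedence = "clinical_feature")
  expect_identical(classify_corpus_terms(docs, lex2)$category,
                   "clinical_feature")
})

test_that("rule-set monotonicity holds", {
  lex <- toy_lexicon()
  tokens <- c("guanylate", "caplacizumab", "thrombosis", "dyspnea",
              "prazosins", "anemia", "kinase")
  full_drugs <- tokens[vapply(tokens, is_drug_compound, TRUE, lexicon = lex)]
  # removing a stem rule never adds a drug classification
  lex_minus <- term_lexicon(lex$stem_rules[-1, ], lex$suffix_rules,
                            dictionary = lex$dictionary_words)
  fewer_drugs <- tokens[vapply(tokens, is_drug_compound, TRUE,
                               lexicon = lex_minus)]
  expect_true(all(fewer_drugs %in% full_drugs))
  # adding a suffix rule never removes a feature classification
  feats <- tokens[vapply(tokens, is_clinical_feature, TRUE, lexicon = lex)]
  lex_plus <- term_lexicon(lex$stem_rules, c(lex$suffix_rules, "ase"),
                           dictionary = lex$dictionary_words)
  more_feats <- tokens[vapply(tokens, is_clinical_feature, TRUE,
                              lexicon = lex_plus)]
  expect_true(all(feats %in% more_feats))
})

test_that("the shipped lexicon snapshot loads and behaves", {
  lex <- default_lexicon()
  expect_gt(nrow(lex$stem_rules), 20)
  expect_gt(length(lex$suffix_rules), 20)
  expect_gt(length(lex$dictionary_words), 500)
  expect_true(is_drug_compound("riociguat", lex))
  expect_false(is_drug_compound("thermostat", lex))  # dictionary veto on "-stat"
  expect_true(is_clinical_feature("hypoxemia", lex))
})
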