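# Shared fixtures: tiny corpora and lexicons built in code.

toy_lexicon <- function() {
  term_lexicon(
    stem_rules = data.frame(
      stem = c("guan", "mab", "ciguat", "osin"),
      position = c("prefix", "suffix", "suffix", "infix"),
      stringsAsFactors = FALSE
    ),
    suffix_rules = c("osis", "emia", "pnea"),
    dictionary = c("map", "basis", "lung", "guano", "deep", "vein", "recur")
  )
}

# a processed_document without running the normalizer
pdoc <- function(doc_id, sentences, year = 2020L) {
  sentences <- lapply(sentences, as.character)
  structure(
    list(doc_id = doc_id, year = year,
         tokens = as.character(unlist(sentences)), sentences = sentences),
    class = "processed_document"
  )
}

toy_corpus_df <- function() {
  data.frame(
    doc_id = c("pmid1", "pmid2", "pmid3"),
    year = c(2019L, 2020L, NA),
    title = c("one", "two", "three"),
    abstract = c("Thromboses were observed in the lung.",
                 "Riociguat helps. CTEPH is rare.",
                 ""),
    stringsAsFactors = FALSE
  )
}

# independent brute-force recount of the interval-weighted score: direct
# arithmetic on raw token lists, no shared code with the scorer
brute_force_tfidf <- function(docs, term, interval_label, doc_years) {
  toks <- lapply(docs, `[[`, "tokens")
  keep <- lengths(toks) > 0
  toks <- toks[keep]
  doc_years <- doc_years[keep]
  in_interval <- !is.na(doc_years) & as.character(doc_years) == interval_label
  interval_tokens <- unlist(toks[in_interval])
  tf <- sum(interval_tokens == term) / length(interval_tokens)
  n_t <- sum(vapply(toks, function(x) term %in% x, logical(1)))
  if (n_t == 0) return(0)
  df <- n_t / length(toks)
  D_corpus <- sum(!is.na(doc_years))
  D_interval <- sum(in_interval)
  tf * (1 / df) * (D_corpus / D_interval)
}

random_toy_docs <- function(n_docs, vocab = letters[1:8], years = 2018:2020) {
  lapply(seq_len(n_docs), function(i) {
    n_tok <- sample(3:30, 1)
    toks <- sample(vocab, n_tok, replace = TRUE)
    pdoc(paste0("d", i), list(toks), year = sample(years, 1))
  })
}
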