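#' Specification for a synthetic literature corpus
#'
#' Describes a seeded generator whose output exercises every pipeline stage
#' offline: documents with publication years, a background vocabulary, drug
#' tokens composed from lexicon stems (so the term classifier recovers
#' them), clinical-feature tokens composed from medical suffixes, and a
#' controllable bridge structure. Sentences are the mixing unit: each
#' sentence draws one topic — background prose, drug context, or disease
#' context (the prediction term). A drug-context sentence carries one
#' candidate drug drawn uniformly from the background and bridged drugs, so
#' every candidate has the same expected corpus frequency and a similarity
#' difference cannot be a frequency artifact. `bridging_strength` is the
#' probability that a sentence whose special token is the prediction term or
#' a bridged drug also carries bridge tokens shared between the two.
#' Bridged drugs never share a sentence with the prediction term, so any
#' similarity between them must travel through the bridge tokens.
#'
#' The same spec and seed always generate byte-identical corpora.
#'
#' @param n_docs number of documents.
#' @param years inclusive year range documents are dated from.
#' @param background_vocab_size distinct background filler tokens.
#' @param n_background_drugs drugs appearing only in drug-context sentences.
#' @param n_bridged_drugs drugs appearing only in bridge-context sentences.
#' @param n_direct_drugs drugs allowed to co-occur with the prediction term
#'   (direct associations when this corpus is the query corpus).
#' @param n_features clinical-feature tokens.
#' @param n_bridge_tokens distinct bridge tokens.
#' @param bridging_strength probability in `[0, 1]` that a prediction-term
#'   or bridged-drug sentence carries bridge tokens.
#' @param sentences_per_doc inclusive range of sentences per document.
#' @param tokens_per_sentence inclusive range of filler tokens per sentence.
#' @param topic_weights probabilities of the three sentence topics
#'   (background, drug, disease); normalized internally.
#' @param include_prediction_term set `FALSE` for an associated-disease
#'   corpus that never mentions the prediction term.
#' @param prediction_term the single-token prediction term.
#' @param drug_stems USAN-style suffixes drug tokens are built from (must
#'   appear in the classifying lexicon).
#' @param feature_suffixes medical suffixes feature tokens are built from.
#' @param seed integer seed; all randomness derives from it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs = 200L,
                           years = c(2010L, 2024L),
                           background_vocab_size = 300L,
                           n_background_drugs = 20L,
                           n_bridged_drugs = 5L,
                           n_direct_drugs = 5L,
                           n_features = 8L,
                           n_bridge_tokens = 12L,
                           bridging_strength = 0.9,
                           sentences_per_doc = c(4L, 8L),
                           tokens_per_sentence = c(6L, 12L),
                           topic_weights = c(background = 0.5, drug = 0.3,
                                             disease = 0.2),
                           include_prediction_term = TRUE,
                           prediction_term = "simdisease",
                           drug_stems = c("ciguat", "mab", "arone", "xaban",
                                          "tinib"),
                           feature_suffixes = c("osis", "emia", "pnea",
                                                "itis"),
                           seed = 1L) {
  stopifnot(n_docs >= 0, bridging_strength >= 0, bridging_strength <= 1,
            length(years) == 2, years[1] <= years[2])
  structure(
    list(n_docs = as.integer(n_docs), years = as.integer(years),
         background_vocab_size = as.integer(background_vocab_size),
         n_background_drugs = as.integer(n_background_drugs),
         n_bridged_drugs = as.integer(n_bridged_drugs),
         n_direct_drugs = as.integer(n_direct_drugs),
         n_features = as.integer(n_features),
         n_bridge_tokens = as.integer(n_bridge_tokens),
         bridging_strength = bridging_strength,
         sentences_per_doc = as.integer(sentences_per_doc),
         tokens_per_sentence = as.integer(tokens_per_sentence),
         topic_weights = topic_weights / sum(topic_weights),
         include_prediction_term = isTRUE(include_prediction_term),
         prediction_term = prediction_term,
         drug_stems = drug_stems, feature_suffixes = feature_suffixes,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# deterministic pronounceable roots: consonant-vowel syllables indexed by a
# mixed-radix expansion, so root i is a pure function of i
synth_root <- function(i, syllables = 3L) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  out <- character(syllables)
  i <- as.integer(i)
  for (s in seq_len(syllables)) {
    ci <- i %% length(consonants); i <- i %/% length(consonants)
    vi <- i %% length(vowels); i <- i %/% length(vowels)
    out[s] <- paste0(consonants[ci + 1], vowels[vi + 1])
  }
  paste(out, collapse = "")
}

# vocabulary words must be fixed points of the lemmatizer, classify as the
# intended category under the lexicon, and avoid the dictionary
synth_wordlist <- function(n, make_word, lexicon, taken,
                           want = c("other", "drug_compound",
                                    "clinical_feature")) {
  want <- match.arg(want)
  out <- character(0)
  i <- 0L
  while (length(out) < n) {
    w <- make_word(i)
    i <- i + 1L
    if (i > 1e6) stop("synthetic vocabulary exhausted", call. = FALSE)
    if (w %in% taken || w %in% out) next
    if (lemmatize_token(w) != w) next
    if (classify_token(w, lexicon) != want) next
    out <- c(out, w)
  }
  out
}

#' Generate a synthetic corpus with a ground-truth manifest
#'
#' @param spec a [synthetic_spec()].
#' @param lexicon the `term_lexicon` the planted tokens must classify under;
#'   the shipped [default_lexicon()] by default.
#' @return List with `corpus` (a `lit_corpus`) and `manifest` — the planted
#'   ground truth: `drugs` (all planted drug tokens), `background_drugs`,
#'   `bridged_drugs`, `direct_drugs`, `features`, `bridge_tokens`,
#'   `background_words` and `prediction_term`.
#' @export
generate_corpus <- function(spec, lexicon = default_lexicon()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    expr
  }

  taken <- c(spec$prediction_term, lexicon$dictionary_words)
  background <- synth_wordlist(
    spec$background_vocab_size, function(i) synth_root(i, 3L),
    lexicon, taken, want = "other"
  )
  taken <- c(taken, background)
  bridge_tokens <- synth_wordlist(
    spec$n_bridge_tokens, function(i) paste0("brg", synth_root(i, 2L)),
    lexicon, taken, want = "other"
  )
  taken <- c(taken, bridge_tokens)
  n_drugs <- spec$n_background_drugs + spec$n_bridged_drugs +
    spec$n_direct_drugs
  stems <- rep_len(spec$drug_stems, max(n_drugs, 1L))
  drugs <- synth_wordlist(
    n_drugs,
    function(i) paste0(synth_root(i, 2L), stems[(i %% length(stems)) + 1]),
    lexicon, taken, want = "drug_compound"
  )
  taken <- c(taken, drugs)
  features <- synth_wordlist(
    spec$n_features,
    function(i) paste0(synth_root(i, 2L),
                       spec$feature_suffixes[(i %% length(spec$feature_suffixes)) + 1]),
    lexicon, taken, want = "clinical_feature"
  )

  background_drugs <- utils::head(drugs, spec$n_background_drugs)
  bridged_drugs <- drugs[spec$n_background_drugs +
                           seq_len(spec$n_bridged_drugs)]
  direct_drugs <- utils::tail(drugs, spec$n_direct_drugs)

  docs <- withr_seed({
    lapply(seq_len(spec$n_docs), function(d) {
      n_sent <- sample(spec$sentences_per_doc[1]:spec$sentences_per_doc[2], 1)
      sentences <- vapply(seq_len(n_sent), function(s) {
        make_sentence(spec, background, background_drugs, bridged_drugs,
                      direct_drugs, features, bridge_tokens)
      }, character(1))
      data.frame(
        doc_id = sprintf("SYN%06d", d),
        year = sample(spec$years[1]:spec$years[2], 1),
        title = sprintf("synthetic document %d", d),
        abstract = paste0(sentences, collapse = " "),
        stringsAsFactors = FALSE
      )
    })
  })
  documents <- if (spec$n_docs > 0) do.call(rbind, docs) else empty_documents()
  list(
    corpus = lit_corpus(documents, name = "synthetic"),
    manifest = list(
      drugs = drugs, background_drugs = background_drugs,
      bridged_drugs = bridged_drugs, direct_drugs = direct_drugs,
      features = features, bridge_tokens = bridge_tokens,
      background_words = background,
      prediction_term = if (spec$include_prediction_term) {
        spec$prediction_term
      } else NULL,
      seed = spec$seed
    )
  )
}

make_sentence <- function(spec, background, background_drugs, bridged_drugs,
                          direct_drugs, features, bridge_tokens) {
  n_fill <- sample(spec$tokens_per_sentence[1]:spec$tokens_per_sentence[2], 1)
  fill <- sample(background, n_fill, replace = TRUE)
  topics <- c("background", "drug", "disease")
  weights <- spec$topic_weights
  if (!spec$include_prediction_term) {
    weights["disease"] <- 0
    weights <- weights / sum(weights)
  }
  topic <- sample(topics, 1, prob = weights)
  extra <- switch(topic,
    background = {
      # occasionally a clinical feature in otherwise plain prose
      if (stats::runif(1) < 0.3) sample(features, 1) else character(0)
    },
    drug = {
      # one candidate drug, uniform over background + bridged drugs, so all
      # candidates share the same expected frequency; only bridged drugs
      # ever co-occur with the bridge tokens
      drug <- sample(c(background_drugs, bridged_drugs), 1)
      c(drug,
        if (drug %in% bridged_drugs &&
              stats::runif(1) < spec$bridging_strength) {
          sample(bridge_tokens, 3)
        } else character(0),
        if (stats::runif(1) < 0.3) sample(features, 1) else character(0))
    },
    disease = c(spec$prediction_term,
                if (stats::runif(1) < spec$bridging_strength) {
                  sample(bridge_tokens, 3)
                } else character(0),
                if (stats::runif(1) < 0.3) sample(direct_drugs, 1) else character(0))
  )
  words <- sample(c(fill, extra))
  paste0(paste(words, collapse = " "), ".")
}

#' Simulate a 2x2 cohort table by binomial draws
#'
#' @param n1,p1 cohort-1 size and true outcome probability.
#' @param n2,p2 cohort-2 size and true outcome probability.
#' @param seed integer seed.
#' @return A [contingency_table()].
#' @export
generate_cohort <- function(n1, p1, n2, p2, seed = 1L) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  contingency_table(n1, stats::rbinom(1, n1, p1),
                    n2, stats::rbinom(1, n2, p2))
}

#' Simulate a two-group survival dataset
#'
#' Event times are exponential with the given per-day hazards; each subject
#' is independently censored with probability `censor_rate` at a uniform
#' time before their event; everyone still at risk at `horizon` is
#' administratively censored there.
#'
#' @param n_per_group subjects per group (length 1 or 2).
#' @param hazards per-group exponential hazards (length 2, per day).
#' @param censor_rate probability a subject is randomly censored.
#' @param horizon administrative censoring time (days).
#' @param seed integer seed.
#' @return A [survival_data()] frame with groups `"g1"` and `"g2"`.
#' @export
generate_survival <- function(n_per_group, hazards, censor_rate = 0.1,
                              horizon = 1825, seed = 1L) {
  stopifnot(all(hazards > 0), censor_rate >= 0, censor_rate <= 1)
  n_per_group <- rep_len(as.integer(n_per_group), 2)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(1:2, function(g) {
    n <- n_per_group[g]
    ev_time <- stats::rexp(n, rate = hazards[g])
    is_cens <- stats::runif(n) < censor_rate
    cens_time <- stats::runif(n, 0, pmin(ev_time, horizon))
    time <- ifelse(is_cens, cens_time, pmin(ev_time, horizon))
    event <- as.integer(!is_cens & ev_time <= horizon)
    data.frame(time = pmax(time, 1e-9), event = event,
               group = paste0("g", g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  survival_data(out$time, out$event, out$group)
}
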