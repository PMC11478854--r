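#' Pipeline configuration
#'
#' One object configures the full four-stage flow: acquire/clean/process,
#' TF-IDF ranking, embedding association, tabular export. Can be built in
#' code or read from a JSON file with the same field names.
#'
#' @param query_phrase the disease query the query corpus answers.
#' @param associated_disease the disease supplying the candidate-rich second
#'   corpus (chosen by the user from the mined disease terms).
#' @param prediction_term single token all drug terms are ranked against
#'   (typically the disease abbreviation).
#' @param query_abbreviation optional abbreviation; when given, occurrences
#'   of `query_phrase` in raw text are collapsed onto it before tokenization
#'   so the prediction term is one vocabulary token.
#' @param lexicon a `term_lexicon`; the shipped default when `NULL`.
#' @param embedding an [embedding_config()].
#' @param ngram_min_frequency strict frequency floor for disease-term
#'   n-grams.
#' @param top_k rows kept in ranking tables.
#' @param interval_breaks optional named list of year sets for
#'   [interval_partition()]; calendar years when `NULL`.
#' @param seed integer seed recorded in every output header and threaded to
#'   the embedding trainer.
#' @param output_dir directory the stage runners write into.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(query_phrase = "", associated_disease = "",
                            prediction_term = "", query_abbreviation = NULL,
                            lexicon = NULL, embedding = embedding_config(),
                            ngram_min_frequency = 5L, top_k = 50L,
                            interval_breaks = NULL, seed = 1L,
                            output_dir = ".") {
  structure(
    list(query_phrase = query_phrase,
         associated_disease = associated_disease,
         prediction_term = tolower(prediction_term),
         query_abbreviation = query_abbreviation,
         lexicon = lexicon,
         embedding = embedding,
         ngram_min_frequency = as.integer(ngram_min_frequency),
         top_k = top_k,
         interval_breaks = interval_breaks,
         seed = as.integer(seed),
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  emb <- do.call(embedding_config, as.list(raw$embedding %||% list()))
  args <- raw[setdiff(names(raw), "embedding")]
  do.call(pipeline_config, c(args, list(embedding = emb)))
}

config_fingerprint <- function(config) {
  # fingerprint the analysis-relevant settings; where outputs land is not one
  keep <- setdiff(names(config), c("lexicon", "output_dir"))
  flat <- utils::capture.output(utils::str(config[keep]))
  string_hash32(paste(flat, collapse = "\n"))
}

output_header <- function(config) {
  c(sprintf("# litrx %s", as.character(utils::packageVersion("litrx"))),
    sprintf("# seed=%d config=%s", config$seed, config_fingerprint(config)))
}

write_csv_with_header <- function(df, path, config) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a stage output CSV, skipping the provenance header
#' @param path CSV written by a stage runner.
#' @return data.frame.
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

resolve_lexicon <- function(config) config$lexicon %||% default_lexicon()

phrase_replacements <- function(config) {
  if (is.null(config$query_abbreviation) || !nzchar(config$query_phrase)) {
    return(NULL)
  }
  stats::setNames(tolower(config$query_abbreviation), config$query_phrase)
}

#' Run the ranking stage
#'
#' Normalizes the query corpus, classifies its vocabulary, writes the
#' corpus-wide and interval-weighted TF-IDF tables for drug compounds and
#' clinical features (`drug_rankings.csv`, `feature_rankings.csv`,
#' `term_scores.csv`) and the flanking-n-gram disease-term table
#' (`disease_terms.csv`) into `config$output_dir`. Every file carries a
#' header with the tool version, seed and config fingerprint; reruns with
#' the same inputs and config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param corpus the query `lit_corpus`, or a path to its JSONL file.
#' @return Invisibly, a list with the in-memory tables (`classification`,
#'   `score_table`, `drug_rankings`, `feature_rankings`, `disease_terms`)
#'   and the processed documents.
#' @export
run_rank_stage <- function(config, corpus) {
  if (is.character(corpus)) {
    if (!file.exists(corpus)) {
      stop("query corpus not found at ", corpus,
           "; fetch it with fetch_pubmed() or point to a JSONL file (",
           "read_corpus)", call. = FALSE)
    }
    corpus <- read_corpus(corpus)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  lexicon <- resolve_lexicon(config)
  docs <- normalize_corpus(corpus, phrase_replacements = phrase_replacements(config))
  if (sum(lengths(lapply(docs, `[[`, "tokens"))) == 0) {
    warning("query corpus has no analyzable tokens; writing empty tables")
  }
  classification <- classify_corpus_terms(docs, lexicon)
  table <- build_term_score_table(docs)
  drug_rankings <- rank_terms(table, classification, "drug_compound",
                              config$top_k)
  feature_rankings <- rank_terms(table, classification, "clinical_feature",
                                 config$top_k)
  features <- terms_of_category(classification, "clinical_feature")
  disease_terms <- if (length(features) > 0) {
    filter_and_rank_ngrams(extract_feature_ngrams(docs, features),
                           config$ngram_min_frequency)
  } else {
    data.frame(ngram = character(), n = integer(), feature = character(),
               frequency = integer(), stringsAsFactors = FALSE)
  }
  out <- file.path(config$output_dir,
                   c("drug_rankings.csv", "feature_rankings.csv",
                     "term_scores.csv", "disease_terms.csv"))
  write_csv_with_header(drug_rankings, out[1], config)
  write_csv_with_header(feature_rankings, out[2], config)
  write_csv_with_header(export_scores(table, classification), out[3], config)
  write_csv_with_header(disease_terms, out[4], config)
  invisible(list(docs = docs, classification = classification,
                 score_table = table, drug_rankings = drug_rankings,
                 feature_rankings = feature_rankings,
                 disease_terms = disease_terms, files = out))
}

#' Run the prediction stage
#'
#' Trains the embedding on the merged query + associated corpora, ranks all
#' drug-compound terms in the embedding vocabulary by cosine similarity to
#' the prediction term, splits them into direct/indirect associations by
#' occurrence in the query corpus, attaches any property labels, and writes
#' `associations.csv` into `config$output_dir`.
#'
#' @param config a [pipeline_config()]; `config$embedding$seed` is set from
#'   `config$seed`.
#' @param query_corpus,associated_corpus `lit_corpus` objects (or JSONL
#'   paths).
#' @param property_map optional named character vector or data.frame
#'   (`term`, `label`) of known drug properties.
#' @return Invisibly, a list with `records` (the association table),
#'   `space` and the processed corpora.
#' @export
run_predict_stage <- function(config, query_corpus, associated_corpus,
                              property_map = NULL) {
  if (is.character(query_corpus)) query_corpus <- read_corpus(query_corpus)
  if (is.character(associated_corpus)) {
    associated_corpus <- read_corpus(associated_corpus)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  lexicon <- resolve_lexicon(config)
  repl <- phrase_replacements(config)
  query_docs <- normalize_corpus(query_corpus, phrase_replacements = repl)
  assoc_docs <- normalize_corpus(associated_corpus, phrase_replacements = repl)
  classification <- classify_corpus_terms(c(query_docs, assoc_docs), lexicon)
  drug_terms <- terms_of_category(classification, "drug_compound")
  sentences <- build_training_text(query_docs, assoc_docs)
  emb_config <- config$embedding
  emb_config$seed <- config$seed
  space <- train_embeddings(sentences, emb_config)
  if (!(config$prediction_term %in% embedding_vocabulary(space))) {
    stop("prediction term ", sQuote(config$prediction_term),
         " is below min_count in the merged corpora; consider configuring ",
         "query_abbreviation so the query phrase collapses onto one token",
         call. = FALSE)
  }
  query_vocab <- unique(unlist(lapply(query_docs, `[[`, "tokens")))
  records <- classify_associations(space, drug_terms, query_vocab,
                                   config$prediction_term)
  if (!is.null(property_map)) {
    records <- label_properties(records, property_map)
  }
  path <- file.path(config$output_dir, "associations.csv")
  write_csv_with_header(records, path, config)
  invisible(list(records = records, space = space, query_docs = query_docs,
                 assoc_docs = assoc_docs, files = path))
}
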