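#' Embedding training configuration
#'
#' Hyperparameters for the skip-gram-with-negative-sampling embedding. The
#' defaults (200 dimensions, window 8, minimum token count 5, 5 epochs)
#' follow the literature-mining precedent for scientific-abstract corpora;
#' every value is overridable.
#'
#' @param dim embedding dimensionality.
#' @param window maximum context window, dynamically shrunk per position as
#'   in the classic implementation.
#' @param min_count tokens occurring fewer times than this in the training
#'   text are dropped from the vocabulary (drug terms included: the drug-term
#'   universe downstream is classified drug tokens intersected with the
#'   embedding vocabulary).
#' @param epochs training passes over the sentence sequence.
#' @param negative negative samples per positive pair.
#' @param alpha,min_alpha initial and floor learning rate (linear decay).
#' @param sample frequent-word subsampling threshold; 0 disables.
#' @param seed integer seed for the trainer's private RNG; with a fixed seed
#'   training is single-threaded and bit-reproducible.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(dim = 200L, window = 8L, min_count = 5L,
                             epochs = 5L, negative = 5L, alpha = 0.025,
                             min_alpha = 1e-4, sample = 0, seed = 1L) {
  stopifnot(dim >= 1, window >= 1, min_count >= 1, epochs >= 1, negative >= 0)
  structure(
    list(dim = as.integer(dim), window = as.integer(window),
         min_count = as.integer(min_count), epochs = as.integer(epochs),
         negative = as.integer(negative), alpha = alpha,
         min_alpha = min_alpha, sample = sample, seed = as.integer(seed),
         architecture = "skip-gram-negative-sampling"),
    class = "embedding_config"
  )
}

#' Merge two processed corpora into one training text
#'
#' The embedding is trained on both the query-disease corpus and the
#' associated-disease corpus at once; the training unit is the sentence, so
#' context windows never leap across sentence (or document) boundaries. The
#' order is deterministic: all sentences of the query corpus first, document
#' order preserved, then the associated corpus.
#'
#' @param query_docs,associated_docs lists of `processed_document`.
#' @return List of character vectors (sentences).
#' @export
build_training_text <- function(query_docs, associated_docs = list()) {
  c(unlist(lapply(query_docs, `[[`, "sentences"), recursive = FALSE),
    unlist(lapply(associated_docs, `[[`, "sentences"), recursive = FALSE))
}

#' Train a word-embedding space
#'
#' Fits skip-gram embeddings with negative sampling (a shallow network: one
#' input layer, one linear hidden layer whose weights become the word
#' vectors, one output layer discarded after training) over the sentence
#' sequence. Single-threaded with a seeded private RNG: two runs with the
#' same input and config produce identical vectors.
#'
#' @param sentences list of character vectors, e.g. from
#'   [build_training_text()].
#' @param config an [embedding_config()].
#' @return An `embedding_space`: list with `vectors` (vocabulary x dim
#'   matrix, rownames are tokens), `vocab_counts` and `config`.
#' @export
train_embeddings <- function(sentences, config = embedding_config()) {
  sentences <- sentences[lengths(sentences) > 0]
  if (length(sentences) == 0) stop("empty training text", call. = FALSE)
  counts <- table(unlist(sentences))
  vocab <- sort(names(counts)[counts >= config$min_count])
  if (length(vocab) == 0) {
    stop("no token reaches min_count = ", config$min_count, call. = FALSE)
  }
  index <- stats::setNames(seq_along(vocab) - 1L, vocab)  # 0-based for C++
  encoded <- lapply(sentences, function(s) {
    idx <- index[s]
    as.integer(idx[!is.na(idx)])
  })
  encoded <- encoded[lengths(encoded) > 0]
  vectors <- .sgns_train(
    encoded, length(vocab), as.numeric(counts[vocab]),
    config$dim, config$window, config$negative, config$epochs,
    config$alpha, config$min_alpha, config$sample, config$seed
  )
  rownames(vectors) <- vocab
  structure(
    list(vectors = vectors,
         vocab_counts = stats::setNames(as.integer(counts[vocab]), vocab),
         config = config),
    class = "embedding_space"
  )
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space>", nrow(x$vectors), "tokens x", ncol(x$vectors),
      "dimensions (", x$config$architecture, ", seed", x$config$seed, ")\n")
  invisible(x)
}

#' Tokens in an embedding space
#' @param space an `embedding_space`.
#' @return character vector of vocabulary tokens.
#' @export
embedding_vocabulary <- function(space) {
  rownames(space$vectors)
}

lookup_vector <- function(space, token) {
  if (!(token %in% rownames(space$vectors))) {
    stop("token not in embedding vocabulary: ", token, call. = FALSE)
  }
  space$vectors[token, ]
}

#' Cosine similarity of two tokens
#'
#' @param space an `embedding_space`.
#' @param a,b vocabulary tokens.
#' @return Cosine of the two word vectors, in `[-1, 1]`.
#' @export
similarity <- function(space, a, b) {
  va <- lookup_vector(space, a)
  vb <- lookup_vector(space, b)
  unname(sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2))))
}

#' Classify drug-term associations to the prediction term
#'
#' Depopulates the embedding vocabulary to the drug-compound terms, scores
#' each against the prediction term by cosine similarity, and splits them
#' into direct associations (the drug occurs at least once in the
#' query-phrase corpus — medication already discussed for the disease) and
#' indirect associations (no occurrence there — the repurposing candidates).
#'
#' @param space an `embedding_space`.
#' @param drug_terms character vector of classified drug-compound tokens.
#' @param query_corpus_vocab character vector: every distinct token of the
#'   query-phrase corpus.
#' @param prediction_term the token all drugs are ranked against; must be in
#'   the embedding vocabulary.
#' @return data.frame `drug_term`, `similarity`, `class` (`"direct"` /
#'   `"indirect"`), sorted by similarity descending within each class
#'   (direct block first), with a `label` column of `NA` placeholders filled
#'   by [label_properties()].
#' @export
classify_associations <- function(space, drug_terms, query_corpus_vocab,
                                  prediction_term) {
  if (!(prediction_term %in% rownames(space$vectors))) {
    stop("prediction term not in embedding vocabulary: ", prediction_term,
         call. = FALSE)
  }
  drugs <- intersect(unique(drug_terms), rownames(space$vectors))
  drugs <- setdiff(drugs, prediction_term)
  if (length(drugs) == 0) {
    return(data.frame(drug_term = character(), similarity = numeric(),
                      class = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  sim <- vapply(drugs, similarity, numeric(1), space = space,
                b = prediction_term)
  cls <- ifelse(drugs %in% query_corpus_vocab, "direct", "indirect")
  out <- data.frame(drug_term = drugs, similarity = unname(sim), class = cls,
                    label = NA_character_, stringsAsFactors = FALSE)
  out <- out[order(match(out$class, c("direct", "indirect")),
                   -out$similarity, out$drug_term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach drug-property labels to association records
#'
#' Labels records whose drug term exactly matches (case-insensitively) an
#' entry of a user-supplied property list, e.g. known pro-/anti-thrombotic
#' drugs. No fuzzy matching. Per-(class, label) counts are attached as the
#' `"label_counts"` attribute.
#'
#' @param records output of [classify_associations()].
#' @param property_map named character vector (`names` = drug lemma,
#'   `values` = label) or a data.frame with columns `term`, `label`.
#' @return The records with the `label` column filled where matched.
#' @export
label_properties <- function(records, property_map) {
  if (is.data.frame(property_map)) {
    property_map <- stats::setNames(property_map$label, property_map$term)
  }
  names(property_map) <- tolower(names(property_map))
  hit <- property_map[tolower(records$drug_term)]
  records$label <- ifelse(is.na(hit), records$label, unname(hit))
  counts <- table(records$class[!is.na(records$label)],
                  records$label[!is.na(records$label)])
  attr(records, "label_counts") <- counts
  records
}

#' Read a drug-property list from CSV (columns `term`, `label`)
#' @param path CSV path.
#' @return data.frame with `term` and `label`.
#' @export
read_property_list <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "label") %in% names(out)))
  out$term <- tolower(out$term)
  out
}

#' Save word vectors in the word2vec text format
#'
#' First line `"<vocab> <dim>"`, then one line per token: the token followed
#' by its vector components separated by spaces. Readable by any word-vector
#' tool; [load_embeddings()] restores the space (training config is not
#' persisted).
#'
#' @param space an `embedding_space`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_embeddings <- function(space, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(nrow(space$vectors), ncol(space$vectors)), con)
  lines <- vapply(seq_len(nrow(space$vectors)), function(i) {
    paste(rownames(space$vectors)[i],
          paste(format(space$vectors[i, ], digits = 17, scientific = TRUE,
                       trim = TRUE), collapse = " "))
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Load word vectors from the word2vec text format
#' @param path path written by [save_embeddings()].
#' @return An `embedding_space` (with `vocab_counts` and `config` absent).
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vectors <- t(vapply(parts, function(p) as.numeric(p[-1]),
                      numeric(hdr[2])))
  rownames(vectors) <- vapply(parts, `[`, character(1), 1)
  structure(list(vectors = vectors, vocab_counts = NULL, config = NULL),
            class = "embedding_space")
}
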