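#' Extract n-grams flanking clinical-feature tokens
#'
#' For every occurrence of a feature token, emits every contiguous window of
#' each length in `n_range` that contains the occurrence and fits within the
#' sentence — windows never cross sentence boundaries, and a window
#' containing the feature at its edge counts (the feature need not be
#' centered). Frequencies aggregate over the whole corpus, counting per
#' occurrence, so one document can contribute many counts.
#'
#' @param docs list of `processed_document`.
#' @param features character vector of clinical-feature tokens (non-empty).
#' @param n_range integer vector of window lengths, within 2..5.
#' @return data.frame `ngram` (space-joined window), `n`, `feature` (the
#'   contained feature token the window was emitted for), `frequency`.
#' @examples
#' d <- structure(list(doc_id = "1", year = 2020L,
#'   tokens = c("deep", "vein", "thrombosis", "recur"),
#'   sentences = list(c("deep", "vein", "thrombosis", "recur"))),
#'   class = "processed_document")
#' extract_feature_ngrams(list(d), "thrombosis", n_range = 2L)
#' @export
extract_feature_ngrams <- function(docs, features, n_range = 2:5) {
  stopifnot(length(features) > 0)
  n_range <- sort(unique(as.integer(n_range)))
  if (any(n_range < 2) || any(n_range > 5)) {
    stop("n_range must lie within 2..5", call. = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  for (doc in docs) {
    for (sent in doc$sentences) {
      len <- length(sent)
      hits <- which(sent %in% features)
      for (i in hits) {
        for (n in n_range) {
          if (n > len) next
          starts <- max(1L, i - n + 1L):min(i, len - n + 1L)
          for (s in starts) {
            gram <- paste(sent[s:(s + n - 1L)], collapse = " ")
            key <- paste0(gram, "\x01", sent[i])
            prev <- acc[[key]]
            acc[[key]] <- if (is.null(prev)) 1L else prev + 1L
          }
        }
      }
    }
  }
  keys <- ls(acc, sorted = TRUE)
  if (length(keys) == 0) {
    return(data.frame(ngram = character(), n = integer(),
                      feature = character(), frequency = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\x01", fixed = TRUE)
  ngram <- vapply(parts, `[`, character(1), 1)
  data.frame(
    ngram = ngram,
    n = lengths(strsplit(ngram, " ", fixed = TRUE)),
    feature = vapply(parts, `[`, character(1), 2),
    frequency = vapply(keys, function(k) acc[[k]], integer(1),
                       USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Filter and rank feature n-grams by frequency
#'
#' Keeps n-grams whose corpus frequency is strictly greater than
#' `min_frequency` (the noise floor; frequent n-grams containing clinical
#' features are the disease-term candidates), sorted by frequency
#' descending, ties by shorter length then lexicographic order.
#'
#' @param ngrams output of [extract_feature_ngrams()].
#' @param min_frequency keep only `frequency > min_frequency`. Default 5.
#' @return Filtered, ordered data.frame of the same shape.
#' @export
filter_and_rank_ngrams <- function(ngrams, min_frequency = 5L) {
  stopifnot(min_frequency >= 0)
  out <- ngrams[ngrams$frequency > min_frequency, , drop = FALSE]
  out <- out[order(-out$frequency, out$n, out$ngram), , drop = FALSE]
  rownames(out) <- NULL
  out
}
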