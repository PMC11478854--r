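#' Partition a processed corpus into time intervals
#'
#' Groups documents into publication-time intervals (calendar years by
#' default). Documents whose year is absent are excluded from interval
#' scoring — the interval-weighted score needs an interval document count —
#' and intervals with zero documents are simply not present.
#'
#' @param docs list of `processed_document`.
#' @param breaks optional named list mapping an interval label to the integer
#'   years it covers (year sets must be disjoint); `NULL` means one interval
#'   per calendar year present in the corpus.
#' @return An `interval_partition`: list with `intervals` (named list of
#'   year sets), `doc_interval` (interval label per document, `NA` when the
#'   document has no year or falls outside `breaks`), `D_interval` (document
#'   counts) and `D_corpus` (their sum).
#' @export
interval_partition <- function(docs, breaks = NULL) {
  years <- vapply(docs, function(d) {
    if (is.null(d$year)) NA_integer_ else as.integer(d$year)
  }, integer(1))
  if (is.null(breaks)) {
    present <- sort(unique(years[!is.na(years)]))
    breaks <- stats::setNames(as.list(present), as.character(present))
  }
  all_years <- unlist(breaks)
  if (anyDuplicated(all_years)) {
    stop("interval year sets must be disjoint", call. = FALSE)
  }
  doc_interval <- rep(NA_character_, length(docs))
  for (label in names(breaks)) {
    doc_interval[years %in% breaks[[label]]] <- label
  }
  D_interval <- table(factor(doc_interval, levels = names(breaks)))
  keep <- names(D_interval)[D_interval > 0]   # zero-document intervals skipped
  structure(
    list(intervals = breaks[keep],
         doc_interval = doc_interval,
         D_interval = stats::setNames(as.integer(D_interval[keep]), keep),
         D_corpus = sum(D_interval)),
    class = "interval_partition"
  )
}

#' Build the term-score table for a corpus
#'
#' Tabulates, for every distinct token: its corpus-wide occurrence count,
#' the number of documents it appears in (document frequency numerator), and
#' its per-interval occurrence counts, together with the per-interval and
#' corpus-wide total token counts. These are the ingredients of the
#' interval-weighted TF-IDF
#' \deqn{tf_{interval} \cdot \frac{1}{df_{corpus}} \cdot \frac{D_{corpus}}{D_{interval}}}
#' with `tf` = term occurrences / all tokens (in the interval), `df` =
#' documents containing the term / all documents, and `D` document counts.
#'
#' Documents with zero tokens are excluded throughout; documents with no
#' publication year contribute to corpus-wide statistics but to no interval.
#'
#' @param docs list of `processed_document`.
#' @param partition an [interval_partition()]; built from `docs` with
#'   calendar-year intervals when `NULL`.
#' @return A `term_score_table`.
#' @export
build_term_score_table <- function(docs, partition = NULL) {
  has_tokens <- vapply(docs, function(d) length(d$tokens) > 0, logical(1))
  scored <- docs[has_tokens]
  if (is.null(partition)) partition <- interval_partition(scored)
  doc_interval <- if (length(partition$doc_interval) == length(docs)) {
    partition$doc_interval[has_tokens]
  } else {
    partition$doc_interval
  }
  stopifnot(length(doc_interval) == length(scored))

  vocab <- sort(unique(unlist(lapply(scored, `[[`, "tokens"))))
  labels <- names(partition$D_interval)
  term_index <- stats::setNames(seq_along(vocab), vocab)

  corpus_count <- integer(length(vocab))
  doc_freq <- integer(length(vocab))
  interval_counts <- matrix(
    0L, nrow = length(vocab), ncol = length(labels),
    dimnames = list(vocab, labels)
  )
  interval_token_totals <- stats::setNames(integer(length(labels)), labels)

  for (i in seq_along(scored)) {
    tab <- table(scored[[i]]$tokens)
    idx <- term_index[names(tab)]
    corpus_count[idx] <- corpus_count[idx] + as.integer(tab)
    doc_freq[idx] <- doc_freq[idx] + 1L
    lab <- doc_interval[i]
    if (!is.na(lab) && lab %in% labels) {
      interval_counts[idx, lab] <- interval_counts[idx, lab] + as.integer(tab)
      interval_token_totals[lab] <- interval_token_totals[lab] +
        length(scored[[i]]$tokens)
    }
  }

  structure(
    list(terms = vocab,
         corpus_count = stats::setNames(corpus_count, vocab),
         doc_freq = stats::setNames(doc_freq, vocab),
         n_docs = length(scored),
         corpus_token_total = sum(corpus_count),
         interval_counts = interval_counts,
         interval_token_totals = interval_token_totals,
         partition = partition),
    class = "term_score_table"
  )
}

#' @export
print.term_score_table <- function(x, ...) {
  cat("<term_score_table>", length(x$terms), "terms over", x$n_docs,
      "documents,", length(x$interval_token_totals), "intervals\n")
  invisible(x)
}

df_corpus <- function(term, table) {
  n_t <- table$doc_freq[term]
  if (is.na(n_t) || n_t == 0) return(NA_real_)
  unname(n_t) / table$n_docs
}

#' Interval-weighted TF-IDF of a term
#'
#' Evaluates the interval-weighted score literally as written:
#' `tf_interval * (1 / df_corpus) * (D_corpus / D_interval)` with a raw
#' reciprocal document frequency (no logarithm; see `variant`). A term that
#' occurs nowhere in the corpus scores 0 (the reciprocal-df guard), as does a
#' term absent from the scored interval.
#'
#' @param term token to score.
#' @param interval interval label present in the table's partition.
#' @param table a `term_score_table`.
#' @param variant `"reciprocal"` (default, the literal formula) or `"log"`
#'   for the classical logarithmic IDF `log(1/df)` for comparison.
#' @return Non-negative score.
#' @export
interval_weighted_tfidf <- function(term, interval, table,
                                    variant = c("reciprocal", "log")) {
  variant <- match.arg(variant)
  labels <- names(table$interval_token_totals)
  if (!(interval %in% labels)) {
    stop("unknown interval: ", interval, call. = FALSE)
  }
  cnt <- if (term %in% rownames(table$interval_counts)) {
    table$interval_counts[term, interval]
  } else 0L
  if (cnt == 0) return(0)
  tf <- cnt / table$interval_token_totals[interval]
  df <- df_corpus(term, table)
  if (is.na(df) || df == 0) return(0)
  idf <- if (variant == "reciprocal") 1 / df else log(1 / df)
  ratio <- table$partition$D_corpus / table$partition$D_interval[interval]
  unname(tf * idf * ratio)
}

#' Corpus-wide TF-IDF of a term
#'
#' The single-interval reduction of the interval-weighted score: the whole
#' corpus is one interval, so the document-count ratio is 1 and the score is
#' `tf_corpus / df_corpus`.
#'
#' @inheritParams interval_weighted_tfidf
#' @return Non-negative score; 0 for a term absent from the corpus.
#' @export
corpus_tfidf <- function(term, table, variant = c("reciprocal", "log")) {
  variant <- match.arg(variant)
  cnt <- table$corpus_count[term]
  if (is.na(cnt) || cnt == 0) return(0)
  tf <- unname(cnt) / table$corpus_token_total
  df <- df_corpus(term, table)
  idf <- if (variant == "reciprocal") 1 / df else log(1 / df)
  tf * idf
}

#' Rank the terms of a category by corpus-wide TF-IDF
#'
#' @param table a `term_score_table`.
#' @param classification output of [classify_corpus_terms()].
#' @param category `"drug_compound"` or `"clinical_feature"`.
#' @param top_k truncate to this many terms (`Inf` for all).
#' @return data.frame `term`, `score`, sorted by score descending with ties
#'   broken lexicographically.
#' @export
rank_terms <- function(table, classification, category, top_k = Inf) {
  terms <- intersect(terms_of_category(classification, category), table$terms)
  if (length(terms) == 0) {
    return(data.frame(term = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  score <- vapply(terms, corpus_tfidf, numeric(1), table = table)
  ord <- order(-score, terms)
  out <- data.frame(term = terms[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, n = if (is.finite(top_k)) top_k else nrow(out))
}

#' Export corpus-wide and interval-weighted scores as CSV
#'
#' One row per classified special term: term, category, corpus-wide score,
#' then one column per interval label.
#'
#' @param table a `term_score_table`.
#' @param classification output of [classify_corpus_terms()].
#' @param path output CSV path (`NULL` to just return the data.frame).
#' @param categories which categories to include.
#' @return The score data.frame, invisibly when written.
#' @export
export_scores <- function(table, classification, path = NULL,
                          categories = c("drug_compound", "clinical_feature")) {
  terms <- intersect(classification$term[classification$category %in% categories],
                     table$terms)
  labels <- names(table$interval_token_totals)
  rows <- lapply(terms, function(tm) {
    iv <- vapply(labels, function(lab) {
      interval_weighted_tfidf(tm, lab, table)
    }, numeric(1))
    cbind(data.frame(term = tm,
                     category = classification$category[classification$term == tm],
                     corpus_score = corpus_tfidf(tm, table),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(iv), col.names = labels, check.names = FALSE))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(term = character(), category = character(),
               corpus_score = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$corpus_score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
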