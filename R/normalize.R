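#' Normalize a document into lemmatized token sequences
#'
#' The cleaning pipeline behind all downstream analysis: the abstract is
#' split into sentences, tokenized, and each token is lowercased and
#' lemmatized to its base form — plural nouns to the singular (including
#' Greco-Latin plurals such as "thromboses" to "thrombosis"), inflected verbs
#' to the infinitive. Punctuation tokens are dropped; intra-word hyphens are
#' preserved so that e.g. "anti-thrombotic" stays one token; numerals are
#' retained.
#'
#' The lemmatizer is rule-based: a small irregular-form table plus ordered
#' suffix rules, with a lightweight part-of-speech guess (tokens ending in
#' "-ed"/"-ing" are treated as verbs, everything else defaults to noun).
#'
#' @param doc one row of a corpus's `documents` (a list or one-row
#'   data.frame with `doc_id`, `year`, `abstract`), or a `lit_corpus` of
#'   size one.
#' @param phrase_replacements optional named character vector mapping a
#'   multi-word phrase (case-insensitive) to a single replacement token,
#'   applied to the raw text before tokenization. Used to collapse a query
#'   phrase onto its abbreviation so the prediction term is one vocabulary
#'   token.
#' @param remove_stopwords drop a small English stop-word list after
#'   tokenization. Off by default: inverse document frequency already
#'   down-weights function words for scoring, and stop-word removal is only
#'   an option for embedding training.
#' @return A `processed_document`: list with `doc_id`, `year`, `tokens`
#'   (character vector) and `sentences` (list of character vectors whose
#'   concatenation equals `tokens`).
#' @examples
#' d <- list(doc_id = "1", year = 2020L,
#'           abstract = "Thromboses were observed. Riociguat helps.")
#' normalize_document(d)$tokens
#' @export
normalize_document <- function(doc, phrase_replacements = NULL,
                               remove_stopwords = FALSE) {
  if (inherits(doc, "lit_corpus")) {
    stopifnot(nrow(doc$documents) == 1)
    doc <- as.list(doc$documents[1, ])
  }
  text <- doc$abstract
  if (is.null(text) || is.na(text)) text <- ""
  if (!is.null(phrase_replacements) && nzchar(text)) {
    for (phrase in names(phrase_replacements)) {
      text <- gsub(phrase, phrase_replacements[[phrase]], text,
                   ignore.case = TRUE, fixed = FALSE)
    }
  }
  sentences_raw <- split_sentences(text)
  sentences <- lapply(sentences_raw, function(s) {
    toks <- tokenize_words(s)
    toks <- vapply(toks, lemmatize_token, character(1), USE.NAMES = FALSE)
    toks <- toks[nzchar(toks)]
    if (remove_stopwords) toks <- toks[!(toks %in% english_stopwords)]
    toks
  })
  sentences <- sentences[lengths(sentences) > 0]
  structure(
    list(doc_id = doc$doc_id,
         year = if (is.null(doc$year)) NA_integer_ else as.integer(doc$year),
         tokens = as.character(unlist(sentences)),
         sentences = sentences),
    class = "processed_document"
  )
}

#' Normalize every document of a corpus
#'
#' @param corpus a `lit_corpus`.
#' @inheritParams normalize_document
#' @return List of `processed_document`, one per input document in input
#'   order (documents with empty abstracts yield zero tokens).
#' @export
normalize_corpus <- function(corpus, phrase_replacements = NULL,
                             remove_stopwords = FALSE) {
  validate_corpus(corpus)
  docs <- corpus$documents
  lapply(seq_len(nrow(docs)), function(i) {
    normalize_document(as.list(docs[i, ]),
                       phrase_replacements = phrase_replacements,
                       remove_stopwords = remove_stopwords)
  })
}

#' @export
print.processed_document <- function(x, ...) {
  cat("<processed_document>", x$doc_id, "—", length(x$tokens), "tokens in",
      length(x$sentences), "sentences\n")
  invisible(x)
}

#' Reassemble normalized text from a processed document
#'
#' Joins the lemmatized tokens back into sentence strings. Normalizing the
#' result again is a no-op, which makes the pipeline idempotent.
#'
#' @param pdoc a `processed_document`.
#' @return A single string, sentences joined by ". ".
#' @export
detokenize <- function(pdoc) {
  paste(vapply(pdoc$sentences, paste, character(1), collapse = " "),
        collapse = ". ")
}

split_sentences <- function(text) {
  if (!nzchar(trimws(text))) return(character())
  # terminator followed by whitespace/end; abbreviations are not special-cased
  parts <- strsplit(text, "(?<=[.!?])[\\s]+|(?<=[.!?])$", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

tokenize_words <- function(sentence) {
  s <- tolower(sentence)
  # keep letters, digits and intra-word hyphens; everything else separates
  s <- gsub("[^a-z0-9-]+", " ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  # strip hyphens at token boundaries, drop leftovers that are only hyphens
  toks <- gsub("^-+|-+$", "", toks)
  toks[nzchar(toks)]
}

# irregular forms that the suffix rules would mangle
irregular_lemmas <- c(
  is = "be", are = "be", was = "be", were = "be", been = "be", being = "be",
  am = "be", has = "have", had = "have", having = "have",
  does = "do", did = "do", done = "do", doing = "do",
  goes = "go", went = "go", gone = "go",
  men = "man", women = "woman", children = "child", feet = "foot",
  teeth = "tooth", mice = "mouse", data = "datum", criteria = "criterion",
  bacteria = "bacterium", phenomena = "phenomenon", analyses = "analysis",
  used = "use", uses = "use", using = "use",
  found = "find", shown = "show", showed = "show", taken = "take",
  took = "take", given = "give", gave = "give", made = "make",
  seen = "see", saw = "see", known = "know", knew = "know",
  lungs = "lung", series = "series", species = "species"
)

# words ending in "-oses" that are ordinary plurals, not Greco-Latin "-osis"
oses_plural_exceptions <- c("doses", "noses", "roses", "poses", "hoses",
                            "gloses", "proses", "moroses")

has_vowel <- function(x) grepl("[aeiouy]", x)

lemmatize_token <- function(token) {
  if (!nzchar(token)) return(token)
  if (grepl("^[0-9][0-9.,-]*$", token)) return(token)   # numerals pass through
  hit <- irregular_lemmas[token]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(token)
  # verb guess: -ing / -ed forms back to the infinitive
  if (n >= 5 && endsWith(token, "ing") && has_vowel(substr(token, 1, n - 3))) {
    return(restore_stem(substr(token, 1, n - 3)))
  }
  if (n >= 4 && endsWith(token, "ied")) {
    return(paste0(substr(token, 1, n - 3), "y"))
  }
  if (n >= 4 && endsWith(token, "ed") && !endsWith(token, "eed") &&
      has_vowel(substr(token, 1, n - 2))) {
    return(restore_stem(substr(token, 1, n - 2)))
  }
  # noun default: plural to singular
  if (n >= 6 && endsWith(token, "oses") &&
      !(token %in% oses_plural_exceptions)) {
    return(paste0(substr(token, 1, n - 2), "is"))     # thromboses -> thrombosis
  }
  if (n >= 5 && endsWith(token, "ies")) {
    return(paste0(substr(token, 1, n - 3), "y"))      # arteries -> artery
  }
  if (n >= 5 && grepl("(ss|x|ch|sh|z)es$", token)) {
    return(substr(token, 1, n - 2))                   # stenoses handled above
  }
  if (n >= 4 && endsWith(token, "s") &&
      !grepl("(ss|us|is)$", token)) {
    return(substr(token, 1, n - 1))                   # patients -> patient
  }
  token
}

# after stripping -ed/-ing: undouble a doubled final consonant, or restore a
# dropped final "e" where the stem shape calls for one (Porter-style)
restore_stem <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(stem)
  last2 <- substr(stem, n - 1, n)
  if (grepl("^([bcdfghjkmnpqrtvw])\\1$", last2)) {
    return(substr(stem, 1, n - 1))                    # stopped -> stop (keep ll/ss/zz)
  }
  if (grepl("(at|bl|iz|v|c|u|[^s]s)$", stem) && !grepl("e$", stem)) {
    return(paste0(stem, "e"))                         # observed -> observe
  }
  stem
}

english_stopwords <- c(
  "a", "an", "and", "as", "at", "be", "but", "by", "do", "for", "from",
  "have", "in", "into", "it", "its", "no", "not", "of", "on", "or", "such",
  "that", "the", "their", "then", "there", "these", "they", "this", "to",
  "we", "which", "with"
)
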