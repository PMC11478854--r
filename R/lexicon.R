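#' Build a term lexicon
#'
#' A `term_lexicon` holds the three rule sets that classify normalized tokens
#' into the two special-term categories:
#' * drug compounds — tokens matching a United States Adopted Names (USAN)
#'   approved stem at its declared position (prefix / suffix / infix) while
#'   being absent from an English dictionary (the dictionary veto suppresses
#'   stem collisions with ordinary words);
#' * clinical features — tokens ending in a medical-glossary suffix such as
#'   "-osis", "-emia" or "-pnea".
#'
#' @param stem_rules data.frame with columns `stem` (lowercase letters and
#'   hyphens, length >= 2), `position` (`"prefix"`, `"suffix"` or `"infix"`)
#'   and `label` (optional pharmacologic-class note).
#' @param suffix_rules character vector of lowercase suffixes, each of
#'   length >= 3 (a leading "-" is tolerated and stripped).
#' @param dictionary character vector of common-English words (lowercase);
#'   membership is tested by exact lemma match.
#' @param min_token_length minimum token length for either special category;
#'   shorter tokens are never classified. Default 5, suppressing stem-collision
#'   noise on short words.
#' @param precedence which category wins when a token matches both a stem and
#'   a suffix; drug stems are the more specific signal, so `"drug_compound"`
#'   by default.
#' @return A `term_lexicon`.
#' @seealso [default_lexicon()] for the shipped rule snapshot.
#' @export
term_lexicon <- function(stem_rules, suffix_rules, dictionary = character(),
                         min_token_length = 5L,
                         precedence = c("drug_compound", "clinical_feature")) {
  precedence <- match.arg(precedence)
  stem_rules <- as.data.frame(stem_rules, stringsAsFactors = FALSE)
  stopifnot(all(c("stem", "position") %in% names(stem_rules)))
  if (is.null(stem_rules$label)) stem_rules$label <- ""
  stem_rules$stem <- tolower(gsub("^-|-$", "", stem_rules$stem))
  if (any(nchar(stem_rules$stem) < 2) ||
      any(!grepl("^[a-z-]+$", stem_rules$stem))) {
    stop("stems must be >= 2 characters of letters/hyphens", call. = FALSE)
  }
  if (!all(stem_rules$position %in% c("prefix", "suffix", "infix"))) {
    stop("stem position must be prefix, suffix or infix", call. = FALSE)
  }
  suffix_rules <- tolower(sub("^-", "", suffix_rules))
  if (any(nchar(suffix_rules) < 3)) {
    stop("suffix rules must be >= 3 characters", call. = FALSE)
  }
  dict_env <- new.env(parent = emptyenv(), size = max(16L, length(dictionary)))
  for (w in tolower(dictionary)) assign(w, TRUE, envir = dict_env)
  structure(
    list(stem_rules = stem_rules, suffix_rules = suffix_rules,
         dictionary = dict_env, dictionary_words = tolower(dictionary),
         min_token_length = as.integer(min_token_length),
         precedence = precedence),
    class = "term_lexicon"
  )
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat("<term_lexicon>",
      nrow(x$stem_rules), "drug stems,",
      length(x$suffix_rules), "clinical suffixes,",
      length(x$dictionary_words), "dictionary words",
      "(min token length", paste0(x$min_token_length, ")"), "\n")
  invisible(x)
}

#' Load the shipped lexicon snapshot
#'
#' Reads the default rule files installed with the package: a snapshot of
#' well-known USAN approved stems (`usan_stems.tsv`), a medical-glossary
#' suffix list (`medical_suffixes.txt`) and a compact common-English word
#' list (`dictionary_basic_en.txt`). All three are plain text and meant to be
#' replaced with larger user-supplied files for production runs.
#'
#' @param stems,suffixes,dictionary optional replacement file paths.
#' @inheritParams term_lexicon
#' @return A `term_lexicon`.
#' @export
default_lexicon <- function(stems = NULL, suffixes = NULL, dictionary = NULL,
                            min_token_length = 5L) {
  pkg_file <- function(f) system.file("extdata", f, package = "litrx",
                                      mustWork = TRUE)
  term_lexicon(
    stem_rules = read_stem_lexicon(stems %||% pkg_file("usan_stems.tsv")),
    suffix_rules = read_suffix_rules(suffixes %||% pkg_file("medical_suffixes.txt")),
    dictionary = read_dictionary(dictionary %||% pkg_file("dictionary_basic_en.txt")),
    min_token_length = min_token_length
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a stem lexicon file
#'
#' Tab-separated with a header line: `stem`, `position`, `label`.
#'
#' @param path TSV file path.
#' @return data.frame of stem rules.
#' @export
read_stem_lexicon <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Read a suffix list file (one suffix per line, `#` comments allowed)
#' @param path text file path.
#' @return character vector of suffixes.
#' @export
read_suffix_rules <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a dictionary word list (one word per line)
#' @param path text file path.
#' @return character vector of words.
#' @export
read_dictionary <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  tolower(lines[nzchar(lines) & !startsWith(lines, "#")])
}

in_dictionary <- function(token, lexicon) {
  exists(token, envir = lexicon$dictionary, inherits = FALSE)
}

matches_stem <- function(token, stem, position) {
  switch(position,
    prefix = startsWith(token, stem),
    suffix = endsWith(token, stem),
    infix = {
      # anywhere except flush against either token boundary
      hits <- gregexpr(stem, token, fixed = TRUE)[[1]]
      if (hits[1] == -1) FALSE else {
        any(hits > 1 & (hits + nchar(stem) - 1) < nchar(token))
      }
    }
  )
}

#' Is a token a drug-compound term?
#'
#' True iff the token matches at least one stem rule at its declared
#' position, is absent from the dictionary, and meets the minimum length.
#'
#' @param token a normalized (lowercase lemma) token.
#' @param lexicon a `term_lexicon`.
#' @return logical.
#' @examples
#' lex <- term_lexicon(
#'   data.frame(stem = c("guan", "mab"), position = c("prefix", "suffix")),
#'   suffix_rules = "osis", dictionary = c("map", "basis")
#' )
#' is_drug_compound("guanylate", lex)     # TRUE: "guan-" prefix
#' is_drug_compound("caplacizumab", lex)  # TRUE: "-mab" suffix
#' is_drug_compound("map", lex)           # FALSE
#' @export
is_drug_compound <- function(token, lexicon) {
  if (nchar(token) < lexicon$min_token_length) return(FALSE)
  if (in_dictionary(token, lexicon)) return(FALSE)
  rules <- lexicon$stem_rules
  for (i in seq_len(nrow(rules))) {
    if (matches_stem(token, rules$stem[i], rules$position[i])) return(TRUE)
  }
  FALSE
}

#' Is a token a clinical-feature term?
#'
#' True iff the token ends with at least one medical suffix and meets the
#' minimum length. (No dictionary veto: clinical features are ordinary
#' medical vocabulary.)
#'
#' @inheritParams is_drug_compound
#' @return logical.
#' @export
is_clinical_feature <- function(token, lexicon) {
  if (nchar(token) < lexicon$min_token_length) return(FALSE)
  for (suf in lexicon$suffix_rules) {
    if (endsWith(token, suf) && nchar(token) > nchar(suf)) return(TRUE)
  }
  FALSE
}

#' Classify every distinct token of a processed corpus
#'
#' Maps each distinct token across the documents to exactly one of
#' `drug_compound`, `clinical_feature` or `other`. A token matching both a
#' stem and a suffix goes to the category named by the lexicon's
#' `precedence` (drug by default). The three categories partition the
#' vocabulary.
#'
#' @param docs list of `processed_document` (see [normalize_corpus()]).
#' @param lexicon a `term_lexicon`.
#' @return data.frame with columns `term` and `category`, one row per
#'   distinct token, sorted by term.
#' @export
classify_corpus_terms <- function(docs, lexicon) {
  vocab <- sort(unique(unlist(lapply(docs, `[[`, "tokens"))))
  if (length(vocab) == 0) {
    return(data.frame(term = character(), category = character(),
                      stringsAsFactors = FALSE))
  }
  category <- vapply(vocab, classify_token, character(1), lexicon = lexicon,
                     USE.NAMES = FALSE)
  data.frame(term = vocab, category = category, stringsAsFactors = FALSE)
}

classify_token <- function(token, lexicon) {
  drug <- is_drug_compound(token, lexicon)
  feat <- is_clinical_feature(token, lexicon)
  if (drug && feat) return(lexicon$precedence)
  if (drug) return("drug_compound")
  if (feat) return("clinical_feature")
  "other"
}

#' Extract the terms of one category from a classification
#' @param classification output of [classify_corpus_terms()].
#' @param category `"drug_compound"`, `"clinical_feature"` or `"other"`.
#' @return character vector of terms.
#' @export
terms_of_category <- function(classification, category) {
  classification$term[classification$category == category]
}
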