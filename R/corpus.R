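#' Construct a literature corpus
#'
#' A `lit_corpus` bundles publication metadata records — one row per abstract —
#' with a label (typically the query phrase that produced it) and an optional
#' retrieval date. Only four fields per record are retained: an opaque document
#' identifier (e.g. a PMID), the publication year, the title and the abstract.
#'
#' @param documents data.frame with columns `doc_id` (character, non-empty,
#'   unique), `year` (integer or `NA`), `title` (character), `abstract`
#'   (character; may be empty — such records are excluded from analysis
#'   downstream).
#' @param name corpus label, e.g. the query phrase.
#' @param retrieval_date optional `Date` or date string stamping when the
#'   records were fetched.
#' @return An object of class `lit_corpus`.
#' @examples
#' corp <- lit_corpus(data.frame(
#'   doc_id = c("1", "2"), year = c(2020L, NA),
#'   title = c("A", "B"), abstract = c("Thrombosis was observed.", "")
#' ), name = "toy")
#' n_documents(corp)
#' @export
lit_corpus <- function(documents = empty_documents(), name = "",
                       retrieval_date = NULL) {
  documents <- as.data.frame(documents, stringsAsFactors = FALSE)
  if (nrow(documents) == 0 && ncol(documents) == 0) {
    documents <- empty_documents()
  }
  required <- c("doc_id", "year", "title", "abstract")
  missing <- setdiff(required, names(documents))
  if (length(missing) > 0) {
    stop("corpus documents lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  documents <- documents[required]
  documents$doc_id <- as.character(documents$doc_id)
  documents$year <- suppressWarnings(as.integer(documents$year))
  documents$title <- as.character(documents$title)
  documents$abstract <- as.character(documents$abstract)
  rownames(documents) <- NULL
  out <- structure(
    list(name = name, documents = documents,
         retrieval_date = retrieval_date),
    class = "lit_corpus"
  )
  validate_corpus(out)
  out
}

empty_documents <- function() {
  data.frame(doc_id = character(), year = integer(), title = character(),
             abstract = character(), stringsAsFactors = FALSE)
}

#' Validate a corpus
#'
#' Checks the `lit_corpus` invariants: non-empty unique `doc_id` and, where
#' present, a plausible 4-digit publication year.
#'
#' @param corpus a `lit_corpus`.
#' @return The corpus, invisibly; errors if invalid.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "lit_corpus"))
  docs <- corpus$documents
  if (anyNA(docs$doc_id) || any(!nzchar(docs$doc_id))) {
    stop("corpus contains empty document identifiers", call. = FALSE)
  }
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup) > 0) {
    stop("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  yrs <- docs$year[!is.na(docs$year)]
  if (any(yrs < 1000 | yrs > 9999)) {
    stop("publication years must be 4-digit positive integers", call. = FALSE)
  }
  invisible(corpus)
}

#' @export
print.lit_corpus <- function(x, ...) {
  cat("<lit_corpus>", if (nzchar(x$name)) sQuote(x$name) else "(unnamed)",
      "\n  documents:", nrow(x$documents),
      "\n  with abstract:", sum(nzchar(x$documents$abstract)), "\n")
  if (!is.null(x$retrieval_date)) {
    cat("  retrieved:", format(x$retrieval_date), "\n")
  }
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus a `lit_corpus`.
#' @return Integer document count.
#' @export
n_documents <- function(corpus) {
  nrow(corpus$documents)
}

#' Read a corpus from JSON Lines
#'
#' The on-disk dialect is JSON Lines: one JSON object per line with keys
#' `doc_id`, `year`, `title`, `abstract`. A missing or `null` `year` marks an
#' undated record. Blank lines are not allowed; order is preserved.
#'
#' @param path path to a `.jsonl` file.
#' @param format file dialect; only `"jsonl"` is supported.
#' @return A `lit_corpus` with one document per input line, in file order.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = "jsonl") {
  format <- match.arg(format, "jsonl")
  if (!file.exists(path)) {
    stop("corpus file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) {
        stop("malformed corpus record at line ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (is.null(rec$doc_id)) {
      stop("malformed corpus record at line ", i, ": missing doc_id",
           call. = FALSE)
    }
    recs[[i]] <- data.frame(
      doc_id = as.character(rec$doc_id),
      year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year),
      title = if (is.null(rec$title)) "" else as.character(rec$title),
      abstract = if (is.null(rec$abstract)) "" else as.character(rec$abstract),
      stringsAsFactors = FALSE
    )
  }
  docs <- if (length(recs) > 0) do.call(rbind, recs) else empty_documents()
  name <- sub("\\.jsonl$", "", basename(path))
  lit_corpus(docs, name = name)
}

#' Write a corpus as JSON Lines
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(c, path))`
#' reproduces `c` field for field (an absent year stays absent).
#'
#' @param corpus a `lit_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  docs <- corpus$documents
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    rec <- list(doc_id = docs$doc_id[i])
    if (!is.na(docs$year[i])) rec$year <- docs$year[i]
    rec$title <- docs$title[i]
    rec$abstract <- docs$abstract[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) {
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}
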