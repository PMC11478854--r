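#' Fetch a corpus from PubMed
#'
#' Queries the NCBI Entrez E-utilities for a query phrase (passed verbatim,
#' e.g. including `AND (english[Language])`), downloads the matching
#' publication metadata, and keeps the four retained fields: PMID, the
#' earliest 4-digit publication year found among the record's date fields,
#' title and abstract. Records with no retrievable abstract text are kept but
#' flagged empty (they are treated as inaccessible downstream and excluded
#' from analysis).
#'
#' Results are paged in fixed-size batches with a polite delay, and every raw
#' XML response is cached under `cache_dir`, so a rerun with the same query
#' reads from disk and needs no network. This is the only function in the
#' package that touches the network.
#'
#' @param query Entrez query string.
#' @param max_records maximum number of records to retrieve.
#' @param email contact e-mail forwarded to NCBI, per their usage policy.
#' @param cache_dir directory for cached raw responses; created if absent.
#' @param batch_size records per efetch request.
#' @param delay seconds to sleep between requests.
#' @return A `lit_corpus` stamped with the retrieval date; an empty corpus if
#'   nothing matches.
#' @export
fetch_pubmed <- function(query, max_records = 10000L, email = "",
                         cache_dir = file.path(tempdir(), "litrx-entrez"),
                         batch_size = 200L, delay = 0.4) {
  if (!nzchar(query)) stop("query must be non-empty", call. = FALSE)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"

  search_url <- paste0(
    base, "/esearch.fcgi?db=pubmed&retmax=", as.integer(max_records),
    "&term=", utils::URLencode(query, reserved = TRUE),
    if (nzchar(email)) paste0("&email=", utils::URLencode(email, reserved = TRUE))
  )
  search_xml <- entrez_request(search_url, cache_dir, "esearch")
  ids <- xml2::xml_text(xml2::xml_find_all(search_xml, ".//IdList/Id"))
  ids <- utils::head(ids, max_records)
  if (length(ids) == 0) {
    return(lit_corpus(name = query, retrieval_date = Sys.Date()))
  }

  batches <- split(ids, ceiling(seq_along(ids) / batch_size))
  recs <- list()
  for (b in seq_along(batches)) {
    fetch_url <- paste0(
      base, "/efetch.fcgi?db=pubmed&retmode=xml&id=",
      paste(batches[[b]], collapse = ","),
      if (nzchar(email)) paste0("&email=", utils::URLencode(email, reserved = TRUE))
    )
    doc <- entrez_request(fetch_url, cache_dir, paste0("efetch-", b))
    recs[[b]] <- parse_pubmed_articles(doc)
    if (b < length(batches)) Sys.sleep(delay)
  }
  docs <- do.call(rbind, recs)
  docs <- docs[!duplicated(docs$doc_id), , drop = FALSE]
  lit_corpus(docs, name = query, retrieval_date = Sys.Date())
}

# GET with on-disk caching of the raw response; retries transient failures.
entrez_request <- function(url, cache_dir, tag, retries = 3) {
  key <- sprintf("%s-%s.xml", tag, string_hash32(url))
  cache_file <- file.path(cache_dir, key)
  if (file.exists(cache_file)) {
    return(xml2::read_xml(cache_file))
  }
  for (attempt in seq_len(retries)) {
    res <- tryCatch(xml2::read_xml(url), error = function(e) e)
    if (!inherits(res, "error")) {
      xml2::write_xml(res, cache_file)
      return(res)
    }
    Sys.sleep(2^attempt)
  }
  stop("Entrez request failed after ", retries, " attempts: ",
       conditionMessage(res), " (retriable)", call. = FALSE)
}

parse_pubmed_articles <- function(doc) {
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  out <- lapply(articles, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")),
      collapse = " "
    )
    # earliest 4-digit year across the record's date fields
    year_nodes <- xml2::xml_find_all(
      a, ".//PubDate/Year | .//ArticleDate/Year | .//DateCompleted/Year"
    )
    years <- suppressWarnings(as.integer(xml2::xml_text(year_nodes)))
    years <- years[!is.na(years) & years >= 1000 & years <= 9999]
    data.frame(
      doc_id = pmid,
      year = if (length(years) > 0) min(years) else NA_integer_,
      title = if (is.na(title)) "" else title,
      abstract = trimws(abstract),
      stringsAsFactors = FALSE
    )
  })
  if (length(out) == 0) empty_documents() else do.call(rbind, out)
}

# 32-bit polynomial rolling hash over a string (base 31, mod 2^32, carried in
# doubles which hold it exactly); used for cache keys and config fingerprints.
string_hash32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x01")))
  h <- 17
  for (b in bytes) {
    h <- (h * 31 + b) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
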