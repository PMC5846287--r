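#' Build an inverted index over indexable documents
#'
#' Tokenizes each document with [tokenize()] and assembles the postings and
#' collection statistics every weighting model needs: within-document term
#' frequencies `tf`, document lengths `dl`, document count `N`, average
#' document length `avg_dl`, document frequencies `df` and total collection
#' frequencies `F`.
#'
#' Documents that tokenize to nothing still count toward `N` with `dl = 0`.
#' Duplicate document identifiers are a fatal error.
#'
#' @param docs Data frame with columns `docno` and `text` (e.g. from
#'   [read_indexable_corpus()]), or a named character vector of texts keyed
#'   by docno.
#' @param max_token_len Token-length cap passed to [tokenize()].
#' @return An `inverted_index`: list with `postings` (data.table keyed by
#'   `term`, columns `term`, `docno`, `tf`), `doc_length` (named numeric),
#'   `N`, `avg_dl`, and `term_stats` (data.table keyed by `term`, columns
#'   `term`, `df`, `F`).
#' @export
build_index <- function(docs, max_token_len = 20L) {
  if (is.character(docs)) {
    docs <- data.frame(docno = names(docs), text = unname(docs),
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("docno", "text") %in% names(docs)))
  if (anyDuplicated(docs$docno)) {
    stop("duplicate docno: ",
         paste(unique(docs$docno[duplicated(docs$docno)]), collapse = ", "),
         call. = FALSE)
  }
  tok <- lapply(docs$text, tokenize, max_len = max_token_len)
  dl <- vapply(tok, length, integer(1))
  doc_length <- stats::setNames(as.numeric(dl), docs$docno)
  N <- nrow(docs)
  if (N == 0L || sum(dl) == 0L) {
    postings <- data.table::data.table(term = character(0),
                                       docno = character(0), tf = numeric(0))
    term_stats <- data.table::data.table(term = character(0),
                                         df = numeric(0), F = numeric(0))
  } else {
    postings <- data.table::rbindlist(lapply(seq_len(N), function(i) {
      if (dl[i] == 0L) return(NULL)
      t <- table(tok[[i]])
      data.table::data.table(term = names(t), docno = docs$docno[i],
                             tf = as.numeric(t))
    }))
    data.table::setkey(postings, term)
    term_stats <- postings[, list(df = as.numeric(.N), F = sum(tf)),
                           by = term]
    data.table::setkey(term_stats, term)
  }
  structure(
    list(postings = postings, doc_length = doc_length, N = N,
         avg_dl = if (N > 0L) mean(doc_length) else 0,
         term_stats = term_stats),
    class = "inverted_index"
  )
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("<inverted_index> N=", x$N, " docs, ", nrow(x$term_stats),
      " terms, avg_dl=", round(x$avg_dl, 2), "\n", sep = "")
  invisible(x)
}

#' Persist / load an inverted index
#'
#' The on-disk layout is a version-stamped RDS serialization of the index
#' components; `read_index` refuses files with an unknown layout version.
#'
#' @param index An `inverted_index`.
#' @param path File path.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "inverted_index"))
  saveRDS(list(format = "dsetir-index", version = 1L,
               postings = as.data.frame(index$postings),
               doc_length = index$doc_length, N = index$N,
               avg_dl = index$avg_dl,
               term_stats = as.data.frame(index$term_stats)),
          path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "dsetir-index") || !identical(x$version, 1L)) {
    stop("not a recognized index file: ", path, call. = FALSE)
  }
  postings <- data.table::as.data.table(x$postings)
  term_stats <- data.table::as.data.table(x$term_stats)
  if (nrow(postings)) data.table::setkey(postings, term)
  if (nrow(term_stats)) data.table::setkey(term_stats, term)
  structure(list(postings = postings, doc_length = x$doc_length, N = x$N,
                 avg_dl = x$avg_dl, term_stats = term_stats),
            class = "inverted_index")
}
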