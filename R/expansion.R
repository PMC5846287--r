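#' Default stopword list
#'
#' A compact English stoplist applied to query tokens (documents are indexed
#' without stopword removal; only queries are cleaned).
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "could", "did",
    "do", "does", "doing", "down", "during", "each", "few", "for", "from",
    "further", "had", "has", "have", "having", "he", "her", "here", "hers",
    "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
    "itself", "just", "me", "more", "most", "my", "no", "nor", "not", "now",
    "of", "off", "on", "once", "only", "or", "other", "our", "out", "over",
    "own", "same", "she", "should", "so", "some", "such", "than", "that",
    "the", "their", "theirs", "them", "then", "there", "these", "they",
    "this", "those", "through", "to", "too", "under", "until", "up", "very",
    "was", "we", "were", "what", "when", "where", "which", "while", "who",
    "whom", "why", "will", "with", "would", "you", "your", "yours")
}

#' Default non-informative phrase list
#'
#' Boilerplate phrases common in natural-language dataset-search topics
#' ("find data related to ...") that carry no retrieval signal. Removed from
#' queries as whole phrases before stopword removal.
#'
#' @return Character vector of lowercase phrases.
#' @export
default_noise_phrases <- function() {
  c("search for", "looking for", "related to", "find all", "find",
    "datasets", "dataset", "data")
}

#' Clean a raw topic into original query terms
#'
#' Noise phrases are removed first (as whole phrases, case-insensitive, on
#' word boundaries, longest first), then the remainder is tokenized with the
#' index tokenizer and stopword tokens are dropped.
#'
#' @param text Raw single-line topic text.
#' @param stoplist Stopword vector (default [default_stopwords()]).
#' @param noise_phrases Phrase vector (default [default_noise_phrases()]).
#' @return Character vector of lowercase query terms, in topic order
#'   (possibly empty, with a warning when everything was removed from a
#'   non-empty topic).
#' @examples
#' clean_query("Find data related to diabetes in mice")  # diabetes, mice
#' @export
clean_query <- function(text, stoplist = default_stopwords(),
                        noise_phrases = default_noise_phrases()) {
  if (length(text) == 0L || is.na(text)) return(character(0))
  x <- tolower(text)
  had_content <- nzchar(trimws(x))
  for (ph in noise_phrases[order(-nchar(noise_phrases))]) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ph), "\\b")
    x <- gsub(pat, " ", x)
  }
  toks <- tokenize(x)
  toks <- toks[!toks %in% stoplist]
  if (had_content && !length(toks)) {
    warning("query reduced to nothing after cleaning", call. = FALSE)
  }
  toks
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length with nonzero norms.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for zero vector",
                               call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Read / write word2vec text-format embedding files
#'
#' The standard text format: a header line `"<count> <dim>"` followed by one
#' line per term, `"term v1 v2 ... vD"`. Zero-norm vectors are rejected on
#' read (they have no cosine direction).
#'
#' @param path Vector file path.
#' @param source Label for the space (`"pubmed"`, `"collection"`, ...).
#' @param metadata Optional list of declared training metadata (dimensions,
#'   window, minimum count); carried along for provenance only.
#' @return An `embedding_space`: list with `vectors` (matrix, one row per
#'   term), `dim`, `source`, `metadata`.
#' @export
read_word2vec <- function(path, source = "collection", metadata = list()) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  hdr <- suppressWarnings(
    as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || any(is.na(hdr))) {
    stop("not a word2vec text file (bad header): ", path, call. = FALSE)
  }
  n <- hdr[1]; d <- hdr[2]
  body <- lines[-1]
  if (length(body) != n) {
    stop("word2vec header declares ", n, " vectors but file has ",
         length(body), call. = FALSE)
  }
  parts <- strsplit(trimws(body), "\\s+")
  terms <- vapply(parts, `[`, "", 1L)
  mat <- matrix(NA_real_, nrow = n, ncol = d, dimnames = list(terms, NULL))
  for (i in seq_len(n)) {
    vals <- as.numeric(parts[[i]][-1])
    if (length(vals) != d) {
      stop("vector line ", i + 1L, ": expected ", d, " dimensions",
           call. = FALSE)
    }
    mat[i, ] <- vals
  }
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) {
    stop("zero-norm vector(s) in ", path, ": ",
         paste(head(terms[norms == 0], 3), collapse = ", "), call. = FALSE)
  }
  embedding_space(mat, source = source, metadata = metadata)
}

#' @rdname read_word2vec
#' @param space An `embedding_space`.
#' @param digits Decimal digits written per component.
#' @export
write_word2vec <- function(space, path, digits = 6) {
  m <- space$vectors
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con, useBytes = TRUE)
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(nrow(m))) {
    writeLines(paste(rownames(m)[i],
                     paste(sprintf(fmt, m[i, ]), collapse = " ")),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Construct an embedding space from a term-by-dimension matrix
#'
#' @param vectors Numeric matrix with terms as row names; all rows must have
#'   nonzero norm.
#' @param source Space label, e.g. `"pubmed"` or `"collection"`.
#' @param metadata Declared training metadata (list), provenance only.
#' @return An `embedding_space`.
#' @export
embedding_space <- function(vectors, source = "collection",
                            metadata = list()) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("zero-norm vector not admitted", call. = FALSE)
  structure(list(vectors = vectors, dim = ncol(vectors), source = source,
                 metadata = metadata, unit = vectors / norms),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space '", x$source, "'> ", nrow(x$vectors), " terms x ",
      x$dim, " dims\n", sep = "")
  invisible(x)
}

#' Nearest neighbours of a term in an embedding space
#'
#' @param term Query term.
#' @param space An [embedding_space()].
#' @param threshold Minimum cosine similarity.
#' @param max_neighbors Cap on returned neighbours.
#' @return Data frame `term`, `similarity`, sorted by descending similarity
#'   (ties by term); empty when the term is absent from the space.
#' @export
embedding_neighbors <- function(term, space, threshold = 0.8,
                                max_neighbors = 10L) {
  if (!term %in% rownames(space$vectors)) {
    return(data.frame(term = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  u <- space$unit[term, ]
  sims <- drop(space$unit %*% u)
  sims <- sims[names(sims) != term]
  sel <- sims[sims >= threshold]
  ord <- order(-sel, names(sel))
  sel <- sel[head(ord, max_neighbors)]
  data.frame(term = names(sel), similarity = unname(sel),
             stringsAsFactors = FALSE)
}

#' Expansion thresholds and weights
#'
#' Per-source configuration of the weighted embedding expansion: similarity
#' thresholds per space and query-term weights per term source. The default
#' weights (original 100, PubMed-space neighbours 20, collection-space
#' neighbours 1) encode that expansion terms must weigh far less than
#' original terms, and that neighbours from a small collection-trained space
#' are the least trustworthy.
#'
#' @param thresholds Named numeric vector of per-space cosine thresholds.
#'   Values above 1 are legal and disable that space entirely (no cosine
#'   can reach them) — handy for no-op regression runs.
#' @param weights Named numeric vector of per-source query-term weights.
#' @param max_neighbors Per-term, per-space neighbour cap.
#' @return An `expansion_config` list.
#' @export
expansion_config <- function(thresholds = c(pubmed = 0.9, collection = 0.8),
                             weights = c(original = 100, pubmed = 20,
                                         collection = 1),
                             max_neighbors = 10L) {
  stopifnot(all(thresholds > 0), all(weights > 0), max_neighbors >= 1)
  structure(list(thresholds = thresholds, weights = weights,
                 max_neighbors = as.integer(max_neighbors)),
            class = "expansion_config")
}

#' Expand original query terms with weighted embedding neighbours
#'
#' Original terms carry the `original` weight (default 100). Each embedding
#' space contributes, for every original term it contains, the neighbours
#' whose cosine similarity reaches that space's threshold (capped per term),
#' weighted with the space's source weight. A term proposed by several
#' sources (or already present as an original) keeps the maximum weight —
#' never the sum, so agreement between sources cannot out-weigh an original
#' term. Multi-word candidates are split by the index tokenizer, each token
#' inheriting the candidate's weight.
#'
#' @param original_terms Character vector from [clean_query()].
#' @param spaces List of [embedding_space()]s; each space's `source` label
#'   must have an entry in the config's thresholds and weights.
#' @param config An [expansion_config()].
#' @return A [weighted_query()] with source tags `original`,
#'   `pubmed_emb`, `collection_emb`, ...
#' @export
expand_with_embeddings <- function(original_terms, spaces = list(),
                                   config = expansion_config()) {
  stopifnot(length(original_terms) >= 1L)
  cand <- data.frame(term = original_terms,
                     qtw = unname(config$weights["original"]),
                     source = "original", stringsAsFactors = FALSE)
  for (space in spaces) {
    src <- space$source
    thr <- config$thresholds[src]
    w <- config$weights[src]
    if (is.na(thr) || is.na(w)) {
      stop("no threshold/weight configured for embedding source '", src,
           "'", call. = FALSE)
    }
    for (t in original_terms) {
      nb <- embedding_neighbors(t, space, threshold = thr,
                                max_neighbors = config$max_neighbors)
      if (!nrow(nb)) next
      toks <- unlist(lapply(nb$term, tokenize), use.names = FALSE)
      if (!length(toks)) next
      cand <- rbind(cand, data.frame(term = unique(toks), qtw = unname(w),
                                     source = paste0(src, "_emb"),
                                     stringsAsFactors = FALSE))
    }
  }
  # duplicate resolution: keep the maximum weight, original tag wins ties
  cand <- cand[order(cand$term, -cand$qtw,
                     cand$source != "original"), , drop = FALSE]
  cand <- cand[!duplicated(cand$term), , drop = FALSE]
  weighted_query(cand$term, cand$qtw, cand$source)
}

#' Bo1 informativeness weights for candidate expansion terms
#'
#' The Bose-Einstein Bo1 score of a term over a pseudo-relevant document
#' set: `w(t) = tf_x * log2((1 + Pn)/Pn) + log2(1 + Pn)` with
#' `Pn = F(t)/N` (expected frequency under randomness) and `tf_x` the term's
#' frequency in the pseudo-relevant set.
#'
#' @param tf_x Frequency of the term in the pseudo-relevant set.
#' @param F Collection frequency of the term.
#' @param N Number of documents in the collection.
#' @return Numeric Bo1 weight (vectorized).
#' @export
bo1_weight <- function(tf_x, F, N) {
  pn <- F / N
  tf_x * log2((1 + pn) / pn) + log2(1 + pn)
}

#' Pseudo-relevance-feedback parameters
#'
#' @param method `"rocchio"` (parameterized, beta) or `"bo1"`
#'   (parameter-free).
#' @param top_docs Number of top-ranked documents mined (default 2).
#' @param terms_per_doc Expansion terms taken per document (default 2).
#' @param alpha Rocchio weight on the original query (fixed default 1).
#' @param beta Rocchio weight on the feedback terms (default 0.5).
#' @param per_document If `FALSE`, `terms_per_doc * top_docs` candidates are
#'   taken jointly over the pseudo-relevant set instead of per document.
#' @return A `prf_params` list.
#' @export
prf_params <- function(method = c("rocchio", "bo1"), top_docs = 2L,
                       terms_per_doc = 2L, alpha = 1, beta = 0.5,
                       per_document = TRUE) {
  method <- match.arg(method)
  stopifnot(top_docs >= 1, terms_per_doc >= 1, beta >= 0, alpha > 0)
  structure(list(method = method, top_docs = as.integer(top_docs),
                 terms_per_doc = as.integer(terms_per_doc), alpha = alpha,
                 beta = beta, per_document = isTRUE(per_document)),
            class = "prf_params")
}

#' Augment a query by pseudo-relevance feedback
#'
#' Mines the `top_docs` highest-ranked documents of a first retrieval pass
#' for expansion candidates, scores every candidate with the Bo1
#' informativeness weight over the pseudo-relevant set, and keeps the
#' `terms_per_doc` best candidates per document (ties broken
#' alphabetically). Original query terms are always retained.
#'
#' * `rocchio`: every term's final weight is
#'   `alpha * qtw_orig(t)/max(qtw_orig) + beta * w(t)/max(w)` (with
#'   `qtw_orig = 0` for new terms and `w = 0` for terms outside the
#'   candidate set). With `beta = 0` this is a pure max-normalisation of the
#'   original weights — an order-equivalent query, and new terms (weight 0)
#'   are dropped.
#' * `bo1`: expansion terms are added with weight `w(t)/max(w)`; original
#'   weights are left untouched.
#'
#' @param query Original [weighted_query()] (or character vector).
#' @param index The inverted index (source of `F` and `N`).
#' @param first_pass A `ranked_list` from [search()] on `query`.
#' @param params A [prf_params()].
#' @return An augmented [weighted_query()]; expansion terms carry source
#'   `"prf"`.
#' @export
prf_expand <- function(query, index, first_pass, params = prf_params()) {
  q <- .as_weighted_query(query)
  if (nrow(first_pass) == 0L) {
    stop("first-pass ranking is empty; nothing to feed back", call. = FALSE)
  }
  top <- head(first_pass$docno, params$top_docs)
  # term frequencies within the pseudo-relevant set, from the postings
  post <- index$postings[index$postings$docno %in% top, ]
  if (nrow(post) == 0L) return(q)
  tfx_all <- tapply(post$tf, post$term, sum)
  stats_map <- index$term_stats[data.table::data.table(term = names(tfx_all)),
                                on = "term"]
  w_all <- bo1_weight(as.numeric(tfx_all), F = stats_map$F, N = index$N)
  names(w_all) <- names(tfx_all)
  # candidate selection: best terms_per_doc candidates per top document
  new_terms <- character(0)
  if (params$per_document) {
    for (d in top) {
      dterms <- post$term[post$docno == d]
      dterms <- setdiff(dterms, q$term)
      if (!length(dterms)) next
      ws <- w_all[dterms]
      ord <- order(-ws, names(ws))
      new_terms <- union(new_terms,
                         names(ws)[head(ord, params$terms_per_doc)])
    }
  } else {
    pool <- setdiff(names(w_all), q$term)
    ws <- w_all[pool]
    ord <- order(-ws, names(ws))
    new_terms <- names(ws)[head(ord, params$terms_per_doc *
                                  params$top_docs)]
  }
  w_cand <- w_all[unique(c(new_terms, intersect(q$term, names(w_all))))]
  max_w <- if (length(w_cand)) max(w_cand) else 0
  if (params$method == "bo1") {
    if (!length(new_terms) || max_w <= 0) return(q)
    add <- data.frame(term = new_terms,
                      qtw = unname(w_all[new_terms]) / max_w,
                      source = "prf", stringsAsFactors = FALSE)
    add <- add[add$qtw > 0, , drop = FALSE]
    out <- rbind(data.frame(term = q$term, qtw = q$qtw, source = q$source,
                            stringsAsFactors = FALSE), add)
    return(weighted_query(out$term, out$qtw, out$source))
  }
  # rocchio
  all_terms <- union(q$term, new_terms)
  qtw_orig <- stats::setNames(rep(0, length(all_terms)), all_terms)
  qtw_orig[q$term] <- q$qtw
  w_t <- stats::setNames(rep(0, length(all_terms)), all_terms)
  hit <- intersect(all_terms, names(w_cand))
  if (max_w > 0) w_t[hit] <- w_cand[hit] / max_w
  final <- params$alpha * qtw_orig / max(qtw_orig) + params$beta * w_t
  keep <- final > 0
  src <- ifelse(all_terms %in% q$term,
                q$source[match(all_terms, q$term)], "prf")
  weighted_query(all_terms[keep], unname(final[keep]), src[keep])
}

#' Serialize / parse the single-line weighted-query exchange format
#'
#' `qid term^weight term^weight ...` — one query per line, weights attached
#' with `^` so the query bypasses any downstream tokenization.
#'
#' @param query A [weighted_query()].
#' @param qid Query/topic identifier.
#' @return `format_weighted_query` returns the line as a string;
#'   `parse_weighted_query` returns a list `qid`, `query`.
#' @export
format_weighted_query <- function(query, qid = "1") {
  q <- .as_weighted_query(query)
  paste(qid, paste(sprintf("%s^%.6g", q$term, q$qtw), collapse = " "))
}

#' @rdname format_weighted_query
#' @param line A single formatted line.
#' @export
parse_weighted_query <- function(line) {
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  qid <- parts[1]
  body <- parts[-1]
  tw <- strsplit(body, "^", fixed = TRUE)
  terms <- vapply(tw, `[`, "", 1L)
  wts <- vapply(tw, function(x) {
    if (length(x) >= 2L) as.numeric(x[2]) else 1
  }, 0)
  list(qid = qid, query = weighted_query(terms, wts))
}
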