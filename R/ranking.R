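#' Ranking-model hyper-parameters
#'
#' @param c Normalization-2 hyper-parameter (term-frequency normalization
#'   with respect to document length), default 1.
#' @param k1,b BM25/TF-IDF saturation and length-normalization parameters.
#' @return A `model_params` list.
#' @export
model_params <- function(c = 1, k1 = 1.2, b = 0.75) {
  stopifnot(c > 0, k1 > 0, b >= 0, b <= 1)
  structure(list(c = c, k1 = k1, b = b, log_base = 2),
            class = "model_params")
}

#' Available weighting models
#'
#' The core set carries exact, spot-checked formulas; the extended set
#' follows the public divergence-from-randomness framework descriptions
#' (additive constants there may differ between engines, which never affects
#' document ordering).
#'
#' @return List with `core` and `extended` character vectors of model ids.
#' @export
dfr_models <- function() {
  list(core = c("LGD", "InL2", "PL2", "DPH", "BM25", "TFIDF"),
       extended = c("BB2", "IFB2", "In_expB2", "In_expC2", "DLH", "DLH13",
                    "DFRee", "DFR_BM25"))
}

.canon_model <- function(model_id) {
  all <- unlist(dfr_models(), use.names = FALSE)
  hit <- all[tolower(all) == tolower(model_id)]
  if (length(hit) != 1L) {
    stop("unknown weighting model '", model_id, "'; available: ",
         paste(all, collapse = ", "), call. = FALSE)
  }
  hit
}

.log2e <- log2(exp(1))

#' Normalization 2 term frequency
#'
#' `tfn = tf * log2(1 + c * avg_dl / dl)`: the within-document term frequency
#' normalized with respect to document length, used by the Normalization-2
#' DFR models (LGD, InL2, PL2, ...).
#'
#' @param tf Raw within-document term frequency (> 0).
#' @param dl Document length in tokens (> 0).
#' @param avg_dl Average document length in the collection (> 0).
#' @param c Hyper-parameter (> 0), default 1.
#' @return Normalized term frequency (vectorized).
#' @export
tfn <- function(tf, dl, avg_dl, c = 1) {
  if (any(dl <= 0)) stop("tfn: document length must be positive",
                         call. = FALSE)
  stopifnot(avg_dl > 0, c > 0)
  tf * log2(1 + c * avg_dl / dl)
}

#' Score one term occurrence under a weighting model
#'
#' Computes the contribution of a query term occurring `tf` times in a
#' document of length `dl`, given collection statistics, multiplied by the
#' query-term weight `qtw`. All logarithms are base 2. Vectorized over `tf`,
#' `dl`, `df`, `F` and `qtw`.
#'
#' Core model formulas (with `tfn` = Normalization 2, `lambda = df/N`,
#' `lambda_F = F/N`, `K = k1*(1 - b + b*dl/avg_dl)`):
#'
#' * `LGD   = qtw * log2((lambda + tfn)/lambda)`
#' * `InL2  = qtw * tfn/(tfn+1) * log2((N+1)/(df+0.5))`
#' * `PL2   = qtw * 1/(tfn+1) * (tfn*log2(tfn/lambda_F) +
#'            (lambda_F - tfn)*log2(e) + 0.5*log2(2*pi*tfn))`
#' * `DPH   = qtw * (1-tf/dl)^2/(tf+1) * (tf*log2((tf*avg_dl/dl)*(N/F)) +
#'            0.5*log2(2*pi*tf*(1-tf/dl)))`
#' * `BM25  = qtw * log2((N-df+0.5)/(df+0.5)) * (k1+1)*tf/(tf+K)`
#' * `TFIDF = qtw * (k1+1)*tf/(tf+K) * log2(1+N/df)`
#'
#' PL2 requires `lambda_F < 1` (the term rarer than one occurrence per
#' document on average); for terms violating this the model degenerates and
#' the bounded tf-only branch `qtw * tfn/(tfn+1)` is used, with a warning.
#'
#' @param model_id Model name (case-insensitive); see [dfr_models()].
#' @param tf Within-document term frequency (>= 1).
#' @param dl Document length (tokens).
#' @param N Number of documents in the collection.
#' @param avg_dl Average document length.
#' @param df Document frequency of the term.
#' @param F Total collection frequency of the term.
#' @param qtw Query-term weight (> 0), default 1.
#' @param params [model_params()].
#' @return Numeric score vector.
#' @export
score_term <- function(model_id, tf, dl, N, avg_dl, df, F, qtw = 1,
                       params = model_params()) {
  model <- .canon_model(model_id)
  stopifnot(all(tf >= 1), all(dl > 0), N >= 1, avg_dl > 0,
            all(df >= 1), all(F >= 1), all(qtw > 0))
  c <- params$c; k1 <- params$k1; b <- params$b
  t_n <- tfn(tf, dl, avg_dl, c)
  K <- k1 * (1 - b + b * dl / avg_dl)
  switch(model,
    LGD = {
      lambda <- df / N
      qtw * log2((lambda + t_n) / lambda)
    },
    InL2 = qtw * (t_n / (t_n + 1)) * log2((N + 1) / (df + 0.5)),
    PL2 = {
      lambda_f <- F / N
      bad <- lambda_f >= 1
      if (any(bad)) {
        warning("PL2: F >= N for ", sum(bad),
                " term(s); using bounded tf-only fallback", call. = FALSE)
      }
      main <- qtw * (1 / (t_n + 1)) *
        (t_n * log2(t_n / lambda_f) + (lambda_f - t_n) * .log2e +
           0.5 * log2(2 * pi * t_n))
      ifelse(bad, qtw * t_n / (t_n + 1), main)
    },
    DPH = {
      f <- tf / dl
      norm <- (1 - f)^2 / (tf + 1)
      s <- qtw * norm * (tf * log2((tf * avg_dl / dl) * (N / F)) +
                           0.5 * log2(2 * pi * tf * (1 - f)))
      ifelse(f >= 1, 0, s)  # document made of a single repeated term
    },
    BM25 = {
      idf <- log2((N - df + 0.5) / (df + 0.5))
      qtw * idf * ((k1 + 1) * tf) / (tf + K)
    },
    TFIDF = qtw * ((k1 + 1) * tf / (tf + K)) * log2(1 + N / df),
    DFR_BM25 = qtw * ((k1 + 1) * t_n / (k1 + t_n)) *
      log2((N - df + 0.5) / (df + 0.5)),
    IFB2 = qtw * (F + 1) / (df * (t_n + 1)) * t_n *
      log2((N + 1) / (F + 0.5)),
    In_expB2 = {
      n_exp <- N * (1 - ((N - 1) / N)^F)
      qtw * (F + 1) / (n_exp * (t_n + 1)) * t_n *
        log2((N + 1) / (n_exp + 0.5))
    },
    In_expC2 = {
      n_exp <- N * (1 - ((N - 1) / N)^F)
      t_ne <- tf * log(1 + c * avg_dl / dl)  # base-e normalization
      qtw * (F + 1) / (n_exp * (t_ne + 1)) * t_ne *
        log2((N + 1) / (n_exp + 0.5))
    },
    BB2 = {
      stirling <- function(n, m) {
        ifelse(m > 0, (m + 0.5) * log2(n / m) + (n - m) * log2(n), 0)
      }
      s <- qtw * (F + 1) / (df * (t_n + 1)) *
        (-log2(N - 1) - .log2e +
           stirling(N + F - 1, N + F - t_n - 2) - stirling(F, F - t_n))
      ifelse(is.finite(s), s, 0)
    },
    DLH = {
      f <- tf / dl
      s <- qtw * (tf * log2((tf * avg_dl / dl) * (N / F)) +
                    (dl - tf) * log2(1 - f) +
                    0.5 * log2(2 * pi * tf * (1 - f))) / (tf + 0.5)
      ifelse(f >= 1, 0, s)
    },
    DLH13 = {
      f <- tf / dl
      s <- qtw * (tf * log2((tf * avg_dl / dl) * (N / F)) +
                    0.5 * log2(2 * pi * tf * (1 - f))) / (tf + 0.5)
      ifelse(f >= 1, 0, s)
    },
    DFRee = {
      total_tokens <- N * avg_dl
      prior <- tf / dl
      posterior <- (tf + 1) / (dl + 1)
      inv_prior_coll <- total_tokens / F
      norm <- tf * log2(posterior / prior)
      qtw * norm * (tf * (-log2(prior * inv_prior_coll)) +
                      (tf + 1) * log2(posterior * inv_prior_coll) +
                      0.5 * log2(posterior / prior))
    },
    stop("unhandled model ", model, call. = FALSE)
  )
}

#' Construct a weighted query
#'
#' A weighted query is a set of unique terms, each carrying a positive
#' query-term weight `qtw` and a source tag. Duplicate terms passed in have
#' their weights summed (term multiplicity acts as key frequency).
#'
#' @param terms Character vector of (already tokenized) query terms.
#' @param qtw Numeric weights, recycled.
#' @param source Source tags, recycled: `original`, `pubmed_emb`,
#'   `collection_emb` or `prf`.
#' @return A `weighted_query` data frame with columns `term`, `qtw`,
#'   `source`.
#' @export
weighted_query <- function(terms, qtw = 1,
                           source = "original") {
  stopifnot(all(qtw > 0))
  df <- data.frame(term = as.character(terms),
                   qtw = rep_len(as.numeric(qtw), length(terms)),
                   source = rep_len(as.character(source), length(terms)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$term)) {
    agg <- stats::aggregate(qtw ~ term, data = df, FUN = sum)
    src <- df$source[match(agg$term, df$term)]  # first source wins the tag
    df <- data.frame(term = agg$term, qtw = agg$qtw, source = src,
                     stringsAsFactors = FALSE)
  }
  df <- df[order(df$term), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("weighted_query", "data.frame")
  df
}

.as_weighted_query <- function(query) {
  if (inherits(query, "weighted_query")) return(query)
  if (is.character(query)) return(weighted_query(query))
  if (is.data.frame(query) && all(c("term", "qtw") %in% names(query))) {
    return(weighted_query(query$term, query$qtw,
                          query$source %||% "original"))
  }
  stop("cannot interpret query of class ", paste(class(query), collapse = "/"),
       call. = FALSE)
}

#' Rank documents against a (weighted) query
#'
#' Scores every document containing at least one query term as the sum of
#' per-term contributions ([score_term()]) and returns the top `cutoff`
#' documents, sorted by descending score with ties broken by ascending
#' docno.
#'
#' @param query Character vector of terms or a [weighted_query()].
#' @param index An [build_index()] inverted index.
#' @param model Weighting-model id (see [dfr_models()]), default `"LGD"`.
#' @param params [model_params()].
#' @param cutoff Maximum number of rows returned (default 1000).
#' @param topic Topic identifier stamped on the result rows.
#' @param tag Run tag recorded as an attribute.
#' @return A `ranked_list` data frame: `topic`, `docno`, `rank`, `score`.
#' @export
search <- function(query, index, model = "LGD", params = model_params(),
                   cutoff = 1000L, topic = "1", tag = model) {
  stopifnot(inherits(index, "inverted_index"), cutoff >= 1)
  model <- .canon_model(model)
  q <- .as_weighted_query(query)
  empty <- data.frame(topic = character(0), docno = character(0),
                      rank = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ranked_list", "data.frame")
  attr(empty, "run_tag") <- tag
  if (nrow(q) == 0L) {
    warning("empty query; returning empty ranking", call. = FALSE)
    return(empty)
  }
  if (index$N == 0L || nrow(index$postings) == 0L) return(empty)
  hits <- index$postings[data.table::data.table(term = q$term), nomatch = 0L,
                         on = "term"]
  if (nrow(hits) == 0L) return(empty)
  hits <- merge(hits, index$term_stats, by = "term")
  hits$qtw <- q$qtw[match(hits$term, q$term)]
  hits$dl <- index$doc_length[hits$docno]
  hits$s <- score_term(model, tf = hits$tf, dl = hits$dl, N = index$N,
                       avg_dl = index$avg_dl, df = hits$df, F = hits$F,
                       qtw = hits$qtw, params = params)
  # deterministic accumulation: sum per docno in docno/term order
  data.table::setorder(hits, docno, term)
  agg <- hits[, list(score = sum(s)), by = "docno"]
  ord <- order(-agg$score, agg$docno)
  agg <- agg[head(ord, cutoff), ]
  out <- data.frame(topic = topic, docno = agg$docno,
                    rank = seq_len(nrow(agg)), score = agg$score,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  attr(out, "run_tag") <- tag
  out
}
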