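# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (direct formula transcription, naive
# counting) without touching the package's own scoring/evaluation code
# paths, so agreement is evidence rather than tautology.

# term-at-a-time score of a whole corpus under one model, straight from the
# formulas, one document and one term at a time
oracle_scores <- function(model, query, docs, params = model_params()) {
  toks <- lapply(docs$text, function(t) {
    x <- strsplit(tolower(t), "[^a-z0-9]+")[[1]]
    x[nzchar(x)]
  })
  names(toks) <- docs$docno
  dl <- vapply(toks, length, 0L)
  N <- length(toks)
  avg_dl <- mean(dl)
  all_terms <- unique(unlist(toks))
  df <- vapply(all_terms, function(t) sum(vapply(toks, function(d)
    t %in% d, TRUE)), 0)
  FF <- vapply(all_terms, function(t) sum(vapply(toks, function(d)
    sum(d == t), 0)), 0)
  names(df) <- names(FF) <- all_terms
  qterms <- if (is.data.frame(query)) query$term else query
  qw <- if (is.data.frame(query)) query$qtw else rep(1, length(qterms))
  scores <- numeric(0)
  for (d in docs$docno) {
    s <- 0; hit <- FALSE
    for (j in seq_along(qterms)) {
      t <- qterms[j]
      tf <- sum(toks[[d]] == t)
      if (tf == 0) next
      hit <- TRUE
      s <- s + qw[j] * oracle_term_score(model, tf, dl[[d]], N, avg_dl,
                                         df[[t]], FF[[t]], params)
    }
    if (hit) scores[[d]] <- s
  }
  scores
}

oracle_term_score <- function(model, tf, dl, N, avg_dl, df, FF, params) {
  c <- params$c; k1 <- params$k1; b <- params$b
  t_n <- tf * log2(1 + c * avg_dl / dl)
  K <- k1 * (1 - b + b * dl / avg_dl)
  if (model == "LGD") {
    lam <- df / N
    log2((lam + t_n) / lam)
  } else if (model == "InL2") {
    (t_n / (t_n + 1)) * log2((N + 1) / (df + 0.5))
  } else if (model == "PL2") {
    lam <- FF / N
    if (lam >= 1) return(t_n / (t_n + 1))
    (1 / (t_n + 1)) * (t_n * log2(t_n / lam) +
                         (lam - t_n) * log2(exp(1)) +
                         0.5 * log2(2 * pi * t_n))
  } else if (model == "DPH") {
    f <- tf / dl
    if (f >= 1) return(0)
    ((1 - f)^2 / (tf + 1)) * (tf * log2((tf * avg_dl / dl) * (N / FF)) +
                                0.5 * log2(2 * pi * tf * (1 - f)))
  } else if (model == "BM25") {
    log2((N - df + 0.5) / (df + 0.5)) * ((k1 + 1) * tf) / (tf + K)
  } else if (model == "TFIDF") {
    ((k1 + 1) * tf / (tf + K)) * log2(1 + N / df)
  } else {
    stop("oracle has no formula for ", model)
  }
}

# exact AP over graded qrels (relevant = grade >= 1), naive counting
oracle_ap <- function(docnos, qrels_df) {
  rel_docs <- qrels_df$docno[qrels_df$grade >= 1]
  R <- length(rel_docs)
  if (R == 0) return(NA_real_)
  hits <- 0; s <- 0
  for (k in seq_along(docnos)) {
    if (docnos[k] %in% rel_docs) {
      hits <- hits + 1
      s <- s + hits / k
    }
  }
  s / R
}

# exact full-depth NDCG with linear gain, naive
oracle_ndcg <- function(docnos, qrels_df) {
  g <- qrels_df$grade[match(docnos, qrels_df$docno)]
  g[is.na(g) | g < 0] <- 0
  dcg <- sum(g / log2(seq_along(g) + 1))
  ideal <- sort(qrels_df$grade[qrels_df$grade >= 1], decreasing = TRUE)
  if (!length(ideal)) return(NA_real_)
  idcg <- sum(ideal / log2(seq_along(ideal) + 1))
  dcg / idcg
}

# all-pairs cosine similarities of an embedding matrix, naive double loop
oracle_all_pairs_cosine <- function(mat) {
  n <- nrow(mat)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(mat),
                                                rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      u <- mat[i, ]; v <- mat[j, ]
      out[i, j] <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    }
  }
  out
}

# Bo1 informativeness over a candidate vocabulary, naive
oracle_bo1 <- function(term, top_texts, all_texts) {
  tok <- function(t) {
    x <- strsplit(tolower(t), "[^a-z0-9]+")[[1]]
    x[nzchar(x)]
  }
  tfx <- sum(vapply(top_texts, function(t) sum(tok(t) == term), 0))
  FF <- sum(vapply(all_texts, function(t) sum(tok(t) == term), 0))
  N <- length(all_texts)
  pn <- FF / N
  tfx * log2((1 + pn) / pn) + log2(1 + pn)
}
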