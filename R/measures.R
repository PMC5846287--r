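# shared helpers -------------------------------------------------------------

.topic_of <- function(ranked) {
  tp <- unique(ranked$topic)
  if (length(tp) > 1L) {
    stop("ranking mixes topics (", paste(tp, collapse = ", "),
         "); per-topic measures need a single topic", call. = FALSE)
  }
  if (length(tp) == 0L) NA_character_ else tp
}

# qrels rows for this ranking's topic, as fast lookup structures
.topic_qrels <- function(ranked, qrels) {
  tp <- .topic_of(ranked)
  qq <- qrels[qrels$topic == tp | is.na(tp), , drop = FALSE]
  p <- attr(qrels, "p")
  list(
    grade = stats::setNames(qq$grade, qq$docno),      # includes -1 rows
    stratum = stats::setNames(qq$stratum, qq$docno),
    p = p,
    judged = qq$docno[qq$grade >= 0L],
    relevant = qq$docno[qq$grade >= 1L],
    rel_grades = qq$grade[qq$grade >= 1L],
    rel_strata = qq$stratum[qq$grade >= 1L]
  )
}

.gain_fun <- function(gain = c("linear", "exponential")) {
  gain <- match.arg(gain)
  if (gain == "linear") function(g) g else function(g) 2^g - 1
}

#' Precision at rank k over graded judgments
#'
#' Counts documents in the top `k` whose grade marks them relevant:
#' `+partial` mode accepts grades 1 and 2, `-partial` mode only grade 2.
#' Unjudged documents and pooled-but-unjudged (`-1`) entries count as
#' non-relevant, and the denominator is `k` even when fewer documents were
#' retrieved.
#'
#' @param ranked A single-topic `ranked_list`.
#' @param qrels A [sampled_qrels()].
#' @param k Rank depth (default 10).
#' @param partial Count grade-1 (partially relevant) documents as relevant
#'   (default `TRUE`).
#' @return Precision in \[0, 1\].
#' @export
precision_at_k <- function(ranked, qrels, k = 10L, partial = TRUE) {
  stopifnot(k >= 1)
  if (nrow(ranked) == 0L) return(0)
  tq <- .topic_qrels(ranked, qrels)
  top <- head(ranked$docno[order(ranked$rank)], k)
  g <- tq$grade[top]
  g[is.na(g)] <- 0L
  rel <- if (partial) g >= 1L else g == 2L
  sum(rel) / k
}

#' Normalized discounted cumulative gain at rank k
#'
#' `DCG = sum_{i<=k} gain(grade_i) / log2(i + 1)` over the ranking (linear
#' gain by default: the gain of a document is its grade; unjudged and `-1`
#' entries gain 0). The ideal DCG places all of the topic's judged-relevant
#' grades in descending order. Topics without any judged-relevant document
#' have no defined NDCG and return `NA` with a warning.
#'
#' @inheritParams precision_at_k
#' @param k Rank depth; `Inf` evaluates the full ranking against the full
#'   ideal.
#' @param gain `"linear"` (gain = grade) or `"exponential"`
#'   (`2^grade - 1`).
#' @return NDCG in \[0, 1\], or `NA` when undefined.
#' @export
ndcg_at_k <- function(ranked, qrels, k = 10L, gain = "linear") {
  stopifnot(k >= 1)
  gf <- .gain_fun(gain)
  tq <- .topic_qrels(ranked, qrels)
  if (length(tq$rel_grades) == 0L) {
    warning("topic ", .topic_of(ranked),
            ": no judged-relevant document; NDCG undefined", call. = FALSE)
    return(NA_real_)
  }
  kk <- if (is.finite(k)) k else max(nrow(ranked), length(tq$rel_grades))
  top <- head(ranked$docno[order(ranked$rank)], kk)
  g <- tq$grade[top]
  g[is.na(g) | g < 0L] <- 0L
  dcg <- if (length(top)) sum(gf(g) / log2(seq_along(top) + 1)) else 0
  ideal <- head(sort(tq$rel_grades, decreasing = TRUE), kk)
  idcg <- sum(gf(ideal) / log2(seq_along(ideal) + 1))
  dcg / idcg
}

#' Exact average precision over graded judgments
#'
#' `AP = (1/R) * sum over retrieved relevant docs of P@rank`, with `R` the
#' number of judged-relevant documents for the topic (retrieved or not) and
#' relevance meaning grade >= 1. The reference measure that [inf_ap()]
#' estimates under sampling.
#'
#' @inheritParams precision_at_k
#' @return AP in \[0, 1\], or `NA` when the topic has no relevant document.
#' @export
average_precision <- function(ranked, qrels) {
  tq <- .topic_qrels(ranked, qrels)
  R <- length(tq$relevant)
  if (R == 0L) {
    warning("topic ", .topic_of(ranked),
            ": no judged-relevant document; AP undefined", call. = FALSE)
    return(NA_real_)
  }
  if (nrow(ranked) == 0L) return(0)
  docs <- ranked$docno[order(ranked$rank)]
  g <- tq$grade[docs]
  g[is.na(g)] <- 0L
  is_rel <- g >= 1L
  if (!any(is_rel)) return(0)
  ranks <- which(is_rel)
  prec <- cumsum(is_rel)[ranks] / ranks
  sum(prec) / R
}

#' Inferred average precision over sampled judgments
#'
#' Estimates average precision when only a random sample of the judgment
#' pool was graded: pool entries marked `-1` were pooled but not judged,
#' and each stratum was sampled at rate `p`. For a sampled-relevant
#' document retrieved at rank `k > 1` the precision above it is estimated
#' as
#'
#' `eP@k = 1/k + ((k-1)/k) * (|pooled above| / (k-1)) *
#'         (r + eps) / (r + n + 2*eps)`
#'
#' with `r` and `n` the sampled relevant/non-relevant counts above rank `k`
#' (each count inverse-probability weighted by its stratum's `1/p`), and
#' `eP@1 = 1`. The estimate is averaged over all sampled-relevant documents
#' of the topic, with zero credit for those not retrieved — at `p = 1` with
#' no `-1` entries this is exactly [average_precision()].
#'
#' @inheritParams precision_at_k
#' @param eps Lidstone smoothing constant (default `1e-5`).
#' @return Estimated AP, or `NA` when no sampled-relevant document exists.
#' @export
inf_ap <- function(ranked, qrels, eps = 1e-5) {
  tq <- .topic_qrels(ranked, qrels)
  R <- length(tq$relevant)
  if (R == 0L) {
    warning("topic ", .topic_of(ranked),
            ": no sampled-relevant document; infAP undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (nrow(ranked) == 0L) return(0)
  docs <- ranked$docno[order(ranked$rank)]
  g <- tq$grade[docs]                       # NA = not pooled at all
  pooled <- !is.na(g)
  inv_p <- 1 / tq$p[tq$stratum[docs]]       # NA where not pooled
  rel <- !is.na(g) & g >= 1L
  nonrel <- !is.na(g) & g == 0L
  cum_pooled <- cumsum(pooled)
  cum_r <- cumsum(ifelse(rel, inv_p, 0))
  cum_n <- cumsum(ifelse(nonrel, inv_p, 0))
  total <- 0
  for (k in which(rel)) {
    if (k == 1L) {
      total <- total + 1
    } else {
      pooled_above <- cum_pooled[k - 1L]
      r <- cum_r[k - 1L]
      n <- cum_n[k - 1L]
      frac <- if (r + n + 2 * eps > 0) (r + eps) / (r + n + 2 * eps) else 0
      total <- total + 1 / k + ((k - 1) / k) *
        (pooled_above / (k - 1)) * frac
    }
  }
  unname(total) / R
}

#' Inferred NDCG over sampled judgments
#'
#' The DCG of a ranking is estimated by inverse-probability weighting: each
#' retrieved sampled-relevant document contributes `gain/discount` scaled
#' by `1/p` of its stratum. The ideal DCG comes from the estimated multiset
#' of relevant grades — for each grade the sampled count divided by its
#' stratum rate, rounded to the nearest integer but never below the
#' observed count — sorted in descending order. The ratio is capped at 1.
#' With `p = 1` this collapses to full-depth [ndcg_at_k()].
#'
#' @inheritParams ndcg_at_k
#' @param k Optional rank depth; default evaluates the full ranking.
#' @return Estimated NDCG in \[0, 1\], or `NA` when undefined.
#' @export
inf_ndcg <- function(ranked, qrels, k = Inf, gain = "linear") {
  gf <- .gain_fun(gain)
  tq <- .topic_qrels(ranked, qrels)
  if (length(tq$rel_grades) == 0L) {
    warning("topic ", .topic_of(ranked),
            ": no sampled-relevant document; infNDCG undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (nrow(ranked) == 0L) return(0)
  docs <- ranked$docno[order(ranked$rank)]
  if (is.finite(k)) docs <- head(docs, k)
  g <- tq$grade[docs]
  inv_p <- 1 / tq$p[tq$stratum[docs]]
  rel <- !is.na(g) & g >= 1L
  idx <- which(rel)
  dcg <- sum(gf(g[idx]) * inv_p[idx] / log2(idx + 1))
  # estimated multiset of relevant grades
  est_counts <- integer(0)
  for (gr in sort(unique(tq$rel_grades), decreasing = TRUE)) {
    sel <- tq$rel_grades == gr
    observed <- sum(sel)
    est <- sum(1 / tq$p[tq$rel_strata[sel]])
    est <- max(observed, as.integer(round(est)))
    est_counts <- c(est_counts, stats::setNames(est, gr))
  }
  ideal <- rep(as.integer(names(est_counts)), est_counts)
  if (is.finite(k)) ideal <- head(ideal, k)
  idcg <- sum(gf(ideal) / log2(seq_along(ideal) + 1))
  min(1, dcg / idcg)
}

#' Evaluate a run against qrels
#'
#' Computes, per topic and averaged, the inferred measures (infAP, infNDCG)
#' and the exact top-10 measures (NDCG@10, P@10 with and without partial
#' relevance). Topics without a single judged-relevant document are
#' excluded from the averages (and listed in the report) rather than scored
#' zero.
#'
#' @param run A multi-topic `ranked_list` (e.g. from [parse_run()]) or a
#'   list of per-topic `ranked_list`s.
#' @param qrels A [sampled_qrels()].
#' @param k Rank depth for the \code{@k} measures (default 10).
#' @param eps Smoothing constant for [inf_ap()].
#' @param gain Gain function for the NDCG-family measures.
#' @return An `eval_report`: list with `per_topic` (data frame), `means`
#'   (named numeric) and `excluded_topics`.
#' @export
evaluate_run <- function(run, qrels, k = 10L, eps = 1e-5, gain = "linear") {
  if (inherits(run, "ranked_list")) {
    topics <- unique(run$topic)
    run <- lapply(topics, function(tp) {
      r <- run[run$topic == tp, , drop = FALSE]
      class(r) <- c("ranked_list", "data.frame")
      r
    })
  }
  rows <- list()
  excluded <- character(0)
  for (r in run) {
    tp <- .topic_of(r)
    tq <- .topic_qrels(r, qrels)
    if (length(tq$rel_grades) == 0L) {
      excluded <- c(excluded, tp)
      next
    }
    rows[[tp]] <- data.frame(
      topic = tp,
      infAP = inf_ap(r, qrels, eps = eps),
      infNDCG = inf_ndcg(r, qrels, gain = gain),
      ndcg_at_k = ndcg_at_k(r, qrels, k = k, gain = gain),
      p_at_k_plus_partial = precision_at_k(r, qrels, k = k, partial = TRUE),
      p_at_k_minus_partial = precision_at_k(r, qrels, k = k,
                                            partial = FALSE),
      stringsAsFactors = FALSE
    )
  }
  per_topic <- if (length(rows)) do.call(rbind, rows) else
    data.frame(topic = character(0), infAP = numeric(0),
               infNDCG = numeric(0), ndcg_at_k = numeric(0),
               p_at_k_plus_partial = numeric(0),
               p_at_k_minus_partial = numeric(0), stringsAsFactors = FALSE)
  rownames(per_topic) <- NULL
  if (length(excluded)) {
    message("evaluate_run: excluded ", length(excluded),
            " topic(s) without judged-relevant documents: ",
            paste(excluded, collapse = ", "))
  }
  means <- if (nrow(per_topic)) colMeans(per_topic[, -1, drop = FALSE]) else
    stats::setNames(rep(NA_real_, 5),
                    c("infAP", "infNDCG", "ndcg_at_k",
                      "p_at_k_plus_partial", "p_at_k_minus_partial"))
  structure(list(per_topic = per_topic, means = means,
                 excluded_topics = excluded, k = k),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$per_topic), " topic(s)",
      if (length(x$excluded_topics))
        paste0(" (", length(x$excluded_topics), " excluded)"), "\n",
      sep = "")
  m <- x$means
  cat(sprintf("  infAP   %.4f   infNDCG %.4f\n", m["infAP"], m["infNDCG"]))
  cat(sprintf("  NDCG@%d %.4f   P@%d(+partial) %.4f   P@%d(-partial) %.4f\n",
              x$k, m["ndcg_at_k"], x$k, m["p_at_k_plus_partial"], x$k,
              m["p_at_k_minus_partial"]))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Per-topic rows followed by a `mean` row.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  df <- report$per_topic
  mean_row <- data.frame(topic = "mean", t(report$means),
                         stringsAsFactors = FALSE)
  names(mean_row) <- names(df)
  out <- rbind(df, mean_row)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
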