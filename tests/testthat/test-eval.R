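test_that("qrels parsing maps fields, keeps -1 and rejects junk", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 d42 2", "1 0 d43 -1", "2 0 d42 0"), path)
  qr <- parse_qrels(path)
  expect_identical(qr$grade[qr$topic == "1" & qr$docno == "d42"], 2L)
  expect_identical(qr$grade[qr$topic == "1" & qr$docno == "d43"], -1L)
  expect_identical(attr(qr, "p"), c(s1 = 1))
  writeLines(c("1 0 d42 2", "1 0 d42 1"), path)
  expect_error(parse_qrels(path), "duplicate")
  writeLines("1 0 d42 7", path)
  expect_error(parse_qrels(path), "grade")
  writeLines("1 0 d42", path)
  expect_error(parse_qrels(path), "line 1")
  # stratified five-column form
  writeLines(c("1 0 a 2 s1", "1 0 b 0 s2"), path)
  qr5 <- parse_qrels(path, p = c(s1 = 1, s2 = 0.5))
  expect_identical(qr5$stratum, c("s1", "s2"))
  # unspecified rates default to exhaustive sampling
  expect_identical(attr(parse_qrels(path), "p"), c(s1 = 1, s2 = 1))
  # an explicit but incomplete rate vector is an error
  expect_error(parse_qrels(path, p = c(s1 = 1)), "missing sampling rate")
})

test_that("precision at k honours partial mode and the fixed denominator", {
  grades <- c(a = 2, b = 2, c = 1, d = 1, e = 0, f = 0, g = 0, h = 0,
              i = 0, j = 0)
  qr <- as_qrels(grades)
  rk <- as_ranking(names(grades))
  expect_equal(precision_at_k(rk, qr, 10, partial = TRUE), 0.4)
  expect_equal(precision_at_k(rk, qr, 10, partial = FALSE), 0.2)
  # empty ranking scores zero; all-2 top scores 1 in both modes
  expect_equal(precision_at_k(rk[0, ], qr, 10), 0)
  qr2 <- as_qrels(stats::setNames(rep(2, 10), names(grades)))
  expect_equal(precision_at_k(rk, qr2, 10, TRUE), 1)
  expect_equal(precision_at_k(rk, qr2, 10, FALSE), 1)
  # unjudged and -1 count as non-relevant; denominator stays k
  qr3 <- as_qrels(c(a = 2, b = -1))
  rk3 <- as_ranking(c("a", "b", "zz"))
  expect_equal(precision_at_k(rk3, qr3, 10), 0.1)
  # -partial never exceeds +partial
  set.seed(77)
  for (i in 1:10) {
    g <- stats::setNames(sample(c(-1, 0, 1, 2), 8, TRUE), letters[1:8])
    qrr <- as_qrels(g)
    rkk <- as_ranking(sample(letters[1:8]))
    expect_lte(precision_at_k(rkk, qrr, 5, FALSE),
               precision_at_k(rkk, qrr, 5, TRUE))
  }
})

test_that("NDCG@k matches the hand-computed example", {
  qr <- as_qrels(c(a = 2, b = 0, c = 1))
  rk <- as_ranking(c("a", "b", "c"))
  # DCG = 2 + 0 + 1/2 = 2.5; ideal [2,1,0] -> 2 + 1/log2(3)
  want <- 2.5 / (2 + 1 / log2(3))
  expect_equal(ndcg_at_k(rk, qr, 3), want, tolerance = 1e-12)
  expect_equal(want, 0.95023, tolerance = 1e-5)
  # ideal ordering scores 1
  rk_ideal <- as_ranking(c("a", "c", "b"))
  expect_equal(ndcg_at_k(rk_ideal, qr, 3), 1)
  # nothing relevant retrieved scores 0
  qr2 <- as_qrels(c(x = 0, y = 0, rel = 2))
  expect_equal(ndcg_at_k(as_ranking(c("x", "y")), qr2, 2), 0)
  # no judged-relevant doc at all: NA with warning
  qr3 <- as_qrels(c(x = 0))
  expect_warning(v <- ndcg_at_k(as_ranking("x"), qr3, 5), "undefined")
  expect_true(is.na(v))
})

test_that("fully judged infAP equals exact AP (epsilon vanishes)", {
  qr <- as_qrels(c(r1 = 2, n1 = 0, r2 = 1))
  rk <- as_ranking(c("r1", "n1", "r2"))
  # AP = (1 + 2/3)/2 = 5/6
  expect_equal(average_precision(rk, qr), 5 / 6, tolerance = 1e-12)
  expect_equal(inf_ap(rk, qr), 5 / 6, tolerance = 1e-4)
  expect_equal(inf_ap(rk, qr), 0.83333, tolerance = 1e-4)
  # single relevant retrieved first: both exactly 1
  qr1 <- as_qrels(c(r = 2, n = 0))
  rk1 <- as_ranking(c("r", "n"))
  expect_equal(inf_ap(rk1, qr1), 1)
  expect_equal(average_precision(rk1, qr1), 1)
})

test_that("relevant documents never retrieved cost both AP and infAP", {
  qr <- as_qrels(c(r1 = 2, r2 = 2, n1 = 0))
  rk <- as_ranking(c("r1", "n1"))  # r2 missing from the ranking
  expect_equal(average_precision(rk, qr), 0.5)
  expect_equal(inf_ap(rk, qr), 0.5, tolerance = 1e-6)
})

test_that("p = 1 equivalence holds to 1e-10 on 50 random fixtures", {
  set.seed(4242)
  for (i in 1:50) {
    n_pool <- 20 + sample.int(20, 1)
    docs <- sprintf("d%03d", seq_len(n_pool + 10))
    grades <- sample(c(0L, 1L, 2L), n_pool, TRUE,
                     prob = c(0.6, 0.2, 0.2))
    if (!any(grades > 0)) grades[1] <- 2L
    qdf <- data.frame(topic = "1", docno = docs[seq_len(n_pool)],
                      grade = grades, stringsAsFactors = FALSE)
    qr <- sampled_qrels(qdf)
    rk <- as_ranking(sample(docs, n_pool))
    expect_equal(inf_ap(rk, qr, eps = 0), oracle_ap(rk$docno, qdf),
                 tolerance = 1e-10)
    expect_equal(inf_ndcg(rk, qr), oracle_ndcg(rk$docno, qdf),
                 tolerance = 1e-10)
    # and the exact implementations agree with the oracles too
    expect_equal(average_precision(rk, qr), oracle_ap(rk$docno, qdf),
                 tolerance = 1e-12)
    expect_equal(ndcg_at_k(rk, qr, k = Inf), oracle_ndcg(rk$docno, qdf),
                 tolerance = 1e-12)
  }
})

test_that("measures are invariant to qrels row order", {
  qdf <- data.frame(topic = "1",
                    docno = c("a", "b", "c", "d", "e"),
                    grade = c(2L, 0L, 1L, -1L, 2L),
                    stringsAsFactors = FALSE)
  rk <- as_ranking(c("c", "a", "d", "b", "e"))
  ref <- c(inf_ap(rk, sampled_qrels(qdf)),
           inf_ndcg(rk, sampled_qrels(qdf)),
           precision_at_k(rk, sampled_qrels(qdf), 3),
           ndcg_at_k(rk, sampled_qrels(qdf), 3))
  set.seed(8)
  for (i in 1:5) {
    perm <- sampled_qrels(qdf[sample(nrow(qdf)), ])
    expect_equal(c(inf_ap(rk, perm), inf_ndcg(rk, perm),
                   precision_at_k(rk, perm, 3), ndcg_at_k(rk, perm, 3)),
                 ref, tolerance = 1e-12)
  }
})

test_that("subsampled pools shrink infAP's judged sets but keep -1 pooled", {
  # hand-checkable: ranks 1..4 = [rel, unjudged(-1), nonrel, rel]
  qdf <- data.frame(topic = "1", docno = c("a", "b", "c", "d"),
                    grade = c(2L, -1L, 0L, 1L), stringsAsFactors = FALSE)
  qr <- sampled_qrels(qdf, p = c(s1 = 0.5))
  rk <- as_ranking(c("a", "b", "c", "d"))
  eps <- 1e-5
  # d at rank 4: pooled above = 3, r = 1/p = 2, n = 1/p = 2
  e4 <- 1 / 4 + (3 / 4) * (3 / 3) * ((2 + eps) / (2 + 2 + 2 * eps))
  want <- (1 + e4) / 2
  expect_equal(inf_ap(rk, qr), want, tolerance = 1e-10)
})

test_that("inf_ndcg scales gains and the ideal by inverse probability", {
  qdf <- data.frame(topic = "1", docno = c("a", "b", "c", "d"),
                    grade = c(2L, 0L, 1L, -1L), stringsAsFactors = FALSE)
  qr <- sampled_qrels(qdf, p = c(s1 = 0.5))
  rk <- as_ranking(c("a", "b", "c"))
  # estimated relevant multiset: two 2s and two 1s (counts / 0.5)
  dcg <- 2 / 0.5 / log2(2) + 1 / 0.5 / log2(4)
  idcg <- 2 + 2 / log2(3) + 1 / log2(4) + 1 / log2(5)
  expect_equal(inf_ndcg(rk, qr), min(1, dcg / idcg), tolerance = 1e-12)
  # p = 1: estimator collapses to exact NDCG
  qr1 <- sampled_qrels(qdf[qdf$grade >= 0, ])
  expect_equal(inf_ndcg(rk, qr1), ndcg_at_k(rk, qr1, k = Inf),
               tolerance = 1e-12)
})

test_that("evaluate_run aggregates topics and excludes the unjudged", {
  qdf <- rbind(
    data.frame(topic = "1", docno = c("a", "b"), grade = c(2L, 0L)),
    data.frame(topic = "2", docno = c("a", "b"), grade = c(0L, 1L)),
    data.frame(topic = "3", docno = c("a", "b"), grade = c(0L, 0L)))
  qr <- sampled_qrels(qdf)
  runs <- list(as_ranking(c("a", "b"), topic = "1"),
               as_ranking(c("a", "b"), topic = "2"),
               as_ranking(c("a", "b"), topic = "3"))
  expect_message(rep <- evaluate_run(runs, qr), "excluded 1 topic")
  expect_identical(rep$per_topic$topic, c("1", "2"))
  expect_identical(rep$excluded_topics, "3")
  expect_equal(rep$means[["infAP"]],
               mean(rep$per_topic$infAP))
  expect_true(all(rep$per_topic$infAP >= 0 & rep$per_topic$infAP <= 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(rep, path)
  tab <- utils::read.delim(path)
  expect_identical(tab$topic, c("1", "2", "mean"))
})
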