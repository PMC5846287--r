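test_that("clean_query strips noise phrases then stopwords", {
  expect_identical(clean_query("Find data related to diabetes in mice"),
                   c("diabetes", "mice"))
  expect_identical(clean_query(""), character(0))
  expect_warning(out <- clean_query("find data related to"),
                 "reduced to nothing")
  expect_identical(out, character(0))
  # phrase removal happens before tokenization: "related to" goes as a unit
  expect_false("related" %in% clean_query("find data related to liver"))
})

test_that("cosine similarity matches hand values and rejects zeros", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.70711,
               tolerance = 1e-5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("word2vec text files round-trip", {
  spec <- fixture_spec(seed = 5, embedding_dim = 8, n_clusters = 2,
                       cluster_size = 3)
  sp <- make_embeddings(spec, source = "pubmed")
  path <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(sp, path, digits = 8)
  sp2 <- read_word2vec(path, source = "pubmed")
  expect_identical(rownames(sp2$vectors), rownames(sp$vectors))
  expect_equal(sp2$vectors, sp$vectors, tolerance = 1e-7)
  # malformed headers and short lines are rejected
  writeLines(c("nonsense", "a 1 2"), path)
  expect_error(read_word2vec(path), "bad header")
  writeLines(c("1 3", "a 1 2"), path)
  expect_error(read_word2vec(path), "expected 3 dimensions")
  writeLines(c("1 2", "a 0 0"), path)
  expect_error(read_word2vec(path), "zero-norm")
})

test_that("planted clusters yield exactly the neighbours above threshold", {
  spec <- fixture_spec(seed = 9, embedding_dim = 16, n_clusters = 3,
                       cluster_size = 4, within_cos = 0.92)
  sp <- make_embeddings(spec)
  sims <- oracle_all_pairs_cosine(sp$vectors)
  for (t in rownames(sp$vectors)) {
    nb <- embedding_neighbors(t, sp, threshold = 0.9, max_neighbors = 10)
    want <- setdiff(names(which(sims[t, ] >= 0.9)), t)
    expect_setequal(nb$term, want)
    # cluster of 4: exactly 3 neighbours
    expect_identical(nrow(nb), 3L)
    expect_equal(nb$similarity,
                 unname(sims[t, nb$term]), tolerance = 1e-12)
  }
  # absent term contributes nothing
  expect_identical(nrow(embedding_neighbors("missing", sp)), 0L)
})

test_that("expansion weights terms 100/20/1 by source and caps neighbours", {
  spec <- fixture_spec(seed = 13, embedding_dim = 16, n_clusters = 2,
                       cluster_size = 4, within_cos = 0.95)
  pub <- make_embeddings(spec, clusters = list(c("gene", "locus", "allele"),
                                               c("liver", "hepatic")),
                         source = "pubmed")
  coll <- make_embeddings(spec, clusters = list(c("gene", "genomic"),
                                                c("liver", "renal")),
                          source = "collection")
  q <- expand_with_embeddings(c("gene", "unseen"), list(pub, coll))
  expect_equal(q$qtw[q$term == "gene"], 100)
  expect_identical(q$source[q$term == "gene"], "original")
  expect_equal(q$qtw[q$term == "unseen"], 100)
  expect_equal(q$qtw[q$term == "locus"], 20)
  expect_identical(q$source[q$term == "locus"], "pubmed_emb")
  expect_equal(q$qtw[q$term == "genomic"], 1)
  expect_identical(q$source[q$term == "genomic"], "collection_emb")
  # liver cluster terms don't appear: not neighbours of the query terms
  expect_false("hepatic" %in% q$term)
  # original weights unchanged, originals never removed
  expect_true(all(c("gene", "unseen") %in% q$term))
})

test_that("duplicates across sources keep the maximum weight", {
  spec <- fixture_spec(seed = 21, embedding_dim = 12, n_clusters = 2,
                       cluster_size = 3, within_cos = 0.95)
  # same neighbour 'shared' reachable from both spaces
  pub <- make_embeddings(spec, clusters = list(c("gene", "shared", "extra"),
                                               c("pad1", "pad2")),
                         source = "pubmed")
  coll <- make_embeddings(spec, clusters = list(c("gene", "shared"),
                                                c("pad3", "pad4")),
                          source = "collection")
  q <- expand_with_embeddings("gene", list(coll, pub))
  expect_identical(sum(q$term == "shared"), 1L)
  expect_equal(q$qtw[q$term == "shared"], 20)  # max(20, 1), not 21
  # an expansion term equal to an original keeps the original weight
  q2 <- expand_with_embeddings(c("gene", "shared"), list(pub))
  expect_equal(q2$qtw[q2$term == "shared"], 100)
  expect_identical(q2$source[q2$term == "shared"], "original")
})

test_that("thresholds above all similarities make expansion a no-op", {
  spec <- fixture_spec(seed = 2, embedding_dim = 12, n_clusters = 2,
                       cluster_size = 3)
  sp <- make_embeddings(spec, clusters = list(c("gene", "locus"),
                                              c("liver", "renal")))
  cfg <- expansion_config(thresholds = c(collection = 1),
                          weights = c(original = 100, collection = 1))
  q <- expand_with_embeddings(c("gene", "liver"), list(sp), cfg)
  expect_setequal(q$term, c("gene", "liver"))
  expect_true(all(q$qtw == 100))
})

test_that("per-term neighbour cap bounds the query size", {
  spec <- fixture_spec(seed = 3, embedding_dim = 12, n_clusters = 1,
                       cluster_size = 8, within_cos = 0.95)
  sp <- make_embeddings(spec, clusters = list(paste0("t", 1:8)))
  cfg <- expansion_config(thresholds = c(collection = 0.9),
                          weights = c(original = 100, collection = 1),
                          max_neighbors = 3)
  q <- expand_with_embeddings("t1", list(sp), cfg)
  expect_identical(nrow(q), 4L)  # original + 3 capped neighbours
  expect_lte(nrow(q), 1 * (1 + 3))
})

test_that("Bo1 ranks the dominant co-occurring term highest", {
  # 'marker' co-occurs heavily with the query term in the top documents
  docs <- data.frame(
    docno = c("d1", "d2", "d3", "d4", "d5"),
    text = c("gene marker marker marker signal",
             "gene marker marker noise signal",
             "other words entirely here",
             "unrelated text block noise",
             "more unrelated filler words"),
    stringsAsFactors = FALSE)
  idx <- build_index(docs)
  first <- search("gene", idx, model = "InL2")
  q <- prf_expand("gene", idx, first,
                  prf_params(method = "bo1", top_docs = 2,
                             terms_per_doc = 2))
  added <- q[q$source == "prf", ]
  expect_true("marker" %in% added$term)
  # brute-force Bo1 over the candidate vocabulary agrees on the winner
  cand <- setdiff(unique(tokenize(paste(docs$text[1:2], collapse = " "))),
                  "gene")
  w <- vapply(cand, oracle_bo1, 0, top_texts = docs$text[1:2],
              all_texts = docs$text)
  expect_identical(added$term[which.max(added$qtw)],
                   names(which.max(w)))
  # normalized weights: the best candidate has weight 1
  expect_equal(max(added$qtw), 1)
})

test_that("PRF adds at most terms_per_doc * top_docs new terms", {
  docs <- toy_corpus(n = 10L, seed = 19)
  idx <- build_index(docs)
  q0 <- weighted_query(c("a", "b"))
  first <- search(q0, idx, model = "LGD")
  q <- prf_expand(q0, idx, first, prf_params(top_docs = 2,
                                             terms_per_doc = 2))
  expect_lte(sum(!q$term %in% q0$term), 4L)
  expect_true(all(q0$term %in% q$term))  # originals always retained
})

test_that("Rocchio with beta = 0 is an order-equivalent rescale", {
  docs <- toy_corpus(n = 10L, seed = 29)
  idx <- build_index(docs)
  q0 <- weighted_query(c("a", "b"), qtw = c(100, 100))
  first <- search(q0, idx, model = "LGD")
  q <- prf_expand(q0, idx, first, prf_params(beta = 0))
  # no new terms survive at weight zero
  expect_setequal(q$term, q0$term)
  expect_true(all(q$qtw == 1))  # alpha * 100/100
  r0 <- search(q0, idx, model = "LGD")
  r1 <- search(q, idx, model = "LGD")
  expect_identical(r0$docno, r1$docno)
  expect_equal(r1$score * 100, r0$score, tolerance = 1e-9)
})

test_that("Rocchio blends normalized original and feedback weights", {
  docs <- data.frame(
    docno = c("d1", "d2", "d3"),
    text = c("gene marker marker", "gene marker filler",
             "plain other words"),
    stringsAsFactors = FALSE)
  idx <- build_index(docs)
  q0 <- weighted_query("gene", qtw = 100)
  first <- search(q0, idx, model = "InL2")
  q <- prf_expand(q0, idx, first,
                  prf_params(method = "rocchio", beta = 0.5))
  expect_true("marker" %in% q$term)
  # original term: alpha*1 + beta*(its normalized Bo1 share)
  expect_gte(q$qtw[q$term == "gene"], 1)
  # feedback-only term: at most beta
  expect_lte(q$qtw[q$term == "marker"], 0.5 + 1e-12)
  expect_error(prf_expand(q0, idx, first[0, ], prf_params()),
               "first-pass")
})

test_that("weighted queries survive the single-line exchange format", {
  q <- weighted_query(c("gene", "marker", "mip"), qtw = c(100, 20, 1))
  line <- format_weighted_query(q, qid = "12")
  expect_match(line, "^12 gene\\^100 marker\\^20 mip\\^1$")
  back <- parse_weighted_query(line)
  expect_identical(back$qid, "12")
  expect_identical(back$query$term, q$term)
  expect_equal(back$query$qtw, q$qtw)
})
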