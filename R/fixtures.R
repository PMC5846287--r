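#' Specification for seeded synthetic fixtures
#'
#' Describes a fully deterministic toy study: a dataset-metadata collection
#' spread over repositories with a known fraction of degenerate
#' (uninformative) records, planted per-topic relevance, an embedding space
#' with planted neighbour clusters, and sampled qrels. The same seed always
#' reproduces byte-identical fixtures.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_docs Number of documents.
#' @param vocab_size Filler vocabulary size (drawn from the packaged English
#'   word list).
#' @param degenerate_frac Fraction of documents given degenerate content
#'   (single cryptic identifier titles, missing keywords/description) that
#'   the informativeness filter must drop.
#' @param repo_mix Named fractions over repository names (must sum to 1).
#' @param n_topics Number of query topics with planted relevant documents.
#' @param theme_size Words per topic theme.
#' @param frac_rel2,frac_rel1 Fractions of informative documents planted as
#'   fully (grade 2) / partially (grade 1) relevant per topic.
#' @param frac_distractor Fraction of non-relevant informative documents
#'   that mention one random theme word once — lexical matches judged
#'   non-relevant, so rankings are imperfect the way real pools are.
#' @param embedding_dim Embedding dimensionality.
#' @param n_clusters,cluster_size Planted neighbour structure of the
#'   synthetic embedding space.
#' @param within_cos Target minimum within-cluster cosine similarity.
#' @param qrels_p Sampling rate for the subsampled qrels variant.
#' @param pool_extra Judged non-relevant documents pooled per topic.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_docs = 200L, vocab_size = 150L,
                         degenerate_frac = 0.1,
                         repo_mix = c(geo = 0.30, dryad = 0.20,
                                      bioproject = 0.20,
                                      arrayexpress = 0.15,
                                      clinicaltrials = 0.15),
                         n_topics = 3L, theme_size = 3L,
                         frac_rel2 = 0.06, frac_rel1 = 0.06,
                         frac_distractor = 0.10,
                         embedding_dim = 20L, n_clusters = 4L,
                         cluster_size = 4L, within_cos = 0.92,
                         qrels_p = 0.5, pool_extra = 30L) {
  stopifnot(abs(sum(repo_mix) - 1) < 1e-8, degenerate_frac >= 0,
            degenerate_frac < 1, embedding_dim >= n_clusters,
            within_cos > 0, within_cos < 1, qrels_p > 0, qrels_p <= 1)
  structure(
    list(seed = as.integer(seed), n_docs = as.integer(n_docs),
         vocab_size = as.integer(vocab_size),
         degenerate_frac = degenerate_frac, repo_mix = repo_mix,
         n_topics = as.integer(n_topics), theme_size = as.integer(theme_size),
         frac_rel2 = frac_rel2, frac_rel1 = frac_rel1,
         frac_distractor = frac_distractor,
         embedding_dim = as.integer(embedding_dim),
         n_clusters = as.integer(n_clusters),
         cluster_size = as.integer(cluster_size), within_cos = within_cos,
         qrels_p = qrels_p, pool_extra = as.integer(pool_extra)),
    class = "fixture_spec"
  )
}

# degenerate content templates observed in real dataset collections: cryptic
# chromosome/taxon/sample identifiers with no keywords and empty or
# single-word descriptions
.degenerate_templates <- function() {
  list(
    list(repository = "dryad", title = "chr19", description = NULL),
    list(repository = "dryad", title = "Chr8", description = NULL),
    list(repository = "bioproject", title = "Sobemovirus", description = NULL),
    list(repository = "bioproject", title = "Alphaflexiviridae",
         description = NULL),
    list(repository = "geo", title = "A375R_RPL10a_vivo__Ronly_vem10d_rep2",
         description = "melanoma"),
    list(repository = "geo", title = "A375_vitro_vehicle_rep3",
         description = "melanoma")
  )
}

.fixture_word_pool <- function() {
  w <- default_english_words()
  setdiff(w, c(default_stopwords(), "find", "data", "dataset", "datasets",
               "related"))
}

# synthetic gene-symbol-like tokens: non-English, hyphenated, MeSH-style
.symbol_pool <- function(n) {
  base <- c("MIP-2", "CD69", "LDLR")
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- sprintf("%s%d-%d",
                   apply(matrix(sample(LETTERS, 3 * (n - length(base)),
                                       replace = TRUE), ncol = 3), 1,
                         paste, collapse = ""),
                   sample(1:9, n - length(base), replace = TRUE),
                   sample(1:99, n - length(base), replace = TRUE))
  c(base, unique(extra))[seq_len(n)]
}

#' Generate a synthetic dataset-metadata collection with known truth
#'
#' Builds `n_docs` documents across the configured repositories. A declared
#' fraction receives degenerate content (template titles such as `"chr19"`,
#' no keywords, empty or single-word descriptions) that the informativeness
#' filter must reject; the rest get well-formed titles, descriptions and —
#' for repositories whose schema has them — keyword lists mixing English
#' words and gene-symbol-style MeSH-only tokens. Per topic, fractions of the
#' informative documents are planted as fully or partially relevant by
#' seeding their descriptions with the topic's theme words.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional path; when given the collection XML is written there.
#' @return A `fixture_collection` list: `docs` (a `dataset_collection`),
#'   `truth` (data frame `docno`, `repository`, `degenerate`, `topic`,
#'   `grade`), `topics` (data frame `topic`, `text`, `theme` — the
#'   natural-language queries), `themes` (list of theme word vectors),
#'   `mesh_symbols` (tokens that only a MeSH lexicon can recognize) and
#'   `filler` (the informative vocabulary).
#' @export
make_collection <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  pool <- .fixture_word_pool()
  need <- spec$n_topics * spec$theme_size + spec$vocab_size
  stopifnot(need <= length(pool))
  words <- sample(pool, need)
  themes <- split(words[seq_len(spec$n_topics * spec$theme_size)],
                  rep(seq_len(spec$n_topics), each = spec$theme_size))
  filler <- words[-seq_len(spec$n_topics * spec$theme_size)]
  symbols <- .symbol_pool(20L)
  mappings <- default_category_mappings()

  n_deg <- round(spec$n_docs * spec$degenerate_frac)
  n_inf <- spec$n_docs - n_deg
  repos <- sample(names(spec$repo_mix), n_inf, replace = TRUE,
                  prob = spec$repo_mix)
  # plant relevance: each informative doc is relevant to at most one topic
  grade <- integer(n_inf)
  topic <- rep(NA_integer_, n_inf)
  for (tp in seq_len(spec$n_topics)) {
    free <- which(is.na(topic))
    n2 <- round(spec$frac_rel2 * n_inf)
    n1 <- round(spec$frac_rel1 * n_inf)
    pick <- sample(free, min(n2 + n1, length(free)))
    topic[pick] <- tp
    grade[pick] <- rep(c(2L, 1L), c(n2, n1))[seq_along(pick)]
  }

  docs <- vector("list", spec$n_docs)
  truth <- vector("list", spec$n_docs)
  sent <- function(n) paste(sample(filler, n, replace = TRUE), collapse = " ")
  for (i in seq_len(n_inf)) {
    repo <- repos[i]
    map <- mappings[[repo]]
    desc_words <- sample(filler, 12, replace = TRUE)
    if (!is.na(topic[i])) {
      th <- themes[[topic[i]]]
      planted <- if (grade[i] == 2L) rep(th, 3) else th[1]
      desc_words <- sample(c(desc_words, planted))
    }
    distract <- NA_character_
    if (is.na(topic[i]) && stats::runif(1) < spec$frac_distractor) {
      # lexical distractor: one theme word, judged non-relevant
      dtp <- sample(spec$n_topics, 1)
      desc_words <- sample(c(desc_words, themes[[dtp]][1]))
      distract <- as.character(dtp)
    }
    meta <- list()
    dk <- map$description_keys
    if (length(dk)) meta[[dk[1]]] <- paste(desc_words, collapse = " ")
    if (length(dk) > 1 && stats::runif(1) < 0.5) {
      meta[[dk[2]]] <- sent(4)
    }
    kk <- map$keyword_keys
    if (length(kk)) {
      meta[[kk[1]]] <- paste(c(sample(symbols, 2), sample(filler, 2)),
                             collapse = " ")
    }
    docno <- sprintf("d%05d", i)
    docs[[i]] <- structure(
      list(docno = docno, title = sent(4 + sample.int(4, 1)),
           repository = repo, metadata = meta),
      class = "dataset_document")
    truth[[i]] <- data.frame(docno = docno, repository = repo,
                             degenerate = FALSE,
                             topic = ifelse(is.na(topic[i]), NA_character_,
                                            as.character(topic[i])),
                             grade = grade[i], distractor = distract,
                             stringsAsFactors = FALSE)
  }
  tmpl <- .degenerate_templates()
  for (j in seq_len(n_deg)) {
    t <- tmpl[[(j - 1L) %% length(tmpl) + 1L]]
    docno <- sprintf("g%05d", j)
    meta <- list()
    if (!is.null(t$description)) {
      dk <- mappings[[t$repository]]$description_keys
      meta[[dk[length(dk)]]] <- t$description
    }
    docs[[n_inf + j]] <- structure(
      list(docno = docno, title = t$title, repository = t$repository,
           metadata = meta),
      class = "dataset_document")
    truth[[n_inf + j]] <- data.frame(docno = docno,
                                     repository = t$repository,
                                     degenerate = TRUE,
                                     topic = NA_character_, grade = 0L,
                                     distractor = NA_character_,
                                     stringsAsFactors = FALSE)
  }
  docs <- structure(docs, class = "dataset_collection",
                    n_skipped = 0L, n_json_errors = 0L)
  topics_df <- data.frame(
    topic = as.character(seq_len(spec$n_topics)),
    text = vapply(themes, function(th) {
      sprintf("Find data related to %s", paste(th, collapse = " "))
    }, ""),
    stringsAsFactors = FALSE
  )
  topics_df$theme <- unname(themes)
  if (!is.null(path)) write_collection(docs, path)
  structure(list(docs = docs, truth = do.call(rbind, truth),
                 topics = topics_df, themes = themes,
                 mesh_symbols = symbols, filler = filler, spec = spec),
            class = "fixture_collection")
}

#' Generate a synthetic embedding space with planted neighbour clusters
#'
#' Cluster base directions are mutually orthogonal; each member vector is
#' its cluster base rotated by a fixed small angle in a random direction,
#' so all within-cluster cosines stay at or above `spec$within_cos` while
#' cross-cluster cosines stay far below any usable threshold. This makes
#' "the neighbours above threshold" an exactly known set.
#'
#' @param spec A [fixture_spec()].
#' @param clusters Optional list of character vectors naming each cluster's
#'   terms (lengths may vary); defaults to synthetic names `c<i>t<j>` with
#'   `n_clusters` clusters of `cluster_size`.
#' @param source Space label (`"collection"` or `"pubmed"`).
#' @param path Optional path to also write the word2vec text file.
#' @return An [embedding_space()].
#' @export
make_embeddings <- function(spec, clusters = NULL, source = "collection",
                            path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1000L)
  if (is.null(clusters)) {
    clusters <- lapply(seq_len(spec$n_clusters), function(i) {
      sprintf("c%dt%d", i, seq_len(spec$cluster_size))
    })
  }
  d <- spec$embedding_dim
  if (length(clusters) > d) {
    stop("embedding dimension ", d, " cannot host ", length(clusters),
         " orthogonal clusters", call. = FALSE)
  }
  terms <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(terms)) stop("cluster terms must be unique",
                                 call. = FALSE)
  # orthonormal cluster bases from a QR decomposition of a random matrix
  base <- qr.Q(qr(matrix(stats::rnorm(d * length(clusters)), nrow = d)))
  # rotate each member by angle theta off its base: pairwise within-cluster
  # cosine >= cos(2*theta)
  theta <- acos(spec$within_cos) / 2
  mat <- matrix(0, nrow = length(terms), ncol = d,
                dimnames = list(terms, NULL))
  row <- 1L
  for (ci in seq_along(clusters)) {
    b <- base[, ci]
    for (t in clusters[[ci]]) {
      w <- stats::rnorm(d)
      w <- w - sum(w * b) * b
      w <- w / sqrt(sum(w^2))
      mat[row, ] <- cos(theta) * b + sin(theta) * w
      row <- row + 1L
    }
  }
  space <- embedding_space(mat, source = source,
                           metadata = list(dimensions = d, window = 5,
                                           min_count = 10,
                                           synthetic = TRUE))
  if (!is.null(path)) write_word2vec(space, path)
  space
}

#' Derive full and subsampled qrels from fixture truth
#'
#' Per topic the judgment pool holds every planted relevant document plus
#' `pool_extra` sampled non-relevant ones. The full variant judges the whole
#' pool (`p = 1`); the subsampled variant keeps each judgment with
#' probability `qrels_p` and marks the rest pooled-but-unjudged (`-1`).
#'
#' @param spec A [fixture_spec()].
#' @param fixture A `fixture_collection` from [make_collection()] (or its
#'   `truth` component).
#' @return List with `full` and `sampled` [sampled_qrels()] and the rate
#'   `p`.
#' @export
make_qrels <- function(spec, fixture) {
  stopifnot(inherits(spec, "fixture_spec"))
  truth <- if (inherits(fixture, "fixture_collection")) fixture$truth else
    fixture
  set.seed(spec$seed + 2000L)
  rows <- list()
  for (tp in as.character(seq_len(spec$n_topics))) {
    rel <- truth[!is.na(truth$topic) & truth$topic == tp &
                   truth$grade > 0L, ]
    nonrel <- truth[is.na(truth$topic) | truth$topic != tp |
                      truth$grade == 0L, ]
    # pool the topic's lexical distractors first (they are what depth
    # pooling of real runs would surface), then random extras
    has_d <- "distractor" %in% names(nonrel)
    dist <- if (has_d) nonrel[!is.na(nonrel$distractor) &
                                nonrel$distractor == tp, ] else nonrel[0, ]
    rest <- if (has_d) nonrel[is.na(nonrel$distractor) |
                                nonrel$distractor != tp, ] else nonrel
    n_extra <- max(0L, min(spec$pool_extra - nrow(dist), nrow(rest)))
    pool0 <- rbind(dist, rest[sample(nrow(rest), n_extra), ])
    rows[[tp]] <- data.frame(
      topic = tp,
      docno = c(rel$docno, pool0$docno),
      grade = c(rel$grade, rep(0L, nrow(pool0))),
      stringsAsFactors = FALSE
    )
  }
  full <- sampled_qrels(do.call(rbind, rows))
  sampled <- subsample_qrels(full, p = spec$qrels_p,
                             seed = spec$seed + 3000L)
  list(full = full, sampled = sampled, p = spec$qrels_p)
}

#' Randomly subsample a fully judged qrels
#'
#' Keeps each judgment with probability `p` and turns the rest into
#' pooled-but-unjudged (`-1`) entries; the resulting object records `p` as
#' its stratum sampling rate, which the inferred measures use for
#' inverse-probability correction.
#'
#' @param qrels A fully judged [sampled_qrels()].
#' @param p Sampling rate in (0, 1].
#' @param seed Integer seed.
#' @return A [sampled_qrels()] with `-1` markers and rate `p`.
#' @export
subsample_qrels <- function(qrels, p, seed = 1L) {
  stopifnot(p > 0, p <= 1)
  set.seed(seed)
  out <- as.data.frame(qrels)
  keep <- stats::runif(nrow(out)) < p
  out$grade[!keep] <- -1L
  sampled_qrels(out, p = stats::setNames(p, unique(out$stratum)))
}

#' Write synthetic MeSH vocabulary XML fixtures
#'
#' Builds a minimal, clearly synthetic MeSH-style XML file following the
#' 2017 schema fragments that [build_mesh_lexicon()] harvests (descriptor /
#' pharmacological-action / qualifier / supplementary-record roots with
#' name elements and concept term lists). Intended for offline tests and
#' demonstrations; it is not NLM data.
#'
#' @param path Output file path.
#' @param names Character vector of descriptor/qualifier/record names.
#' @param synonyms Optional character vector of concept-term synonyms.
#' @param schema One of `"desc"`, `"pa"`, `"qual"`, `"suppl"`.
#' @return `path`, invisibly.
#' @export
make_mesh_fixture <- function(path, names, synonyms = character(0),
                              schema = c("desc", "pa", "qual", "suppl")) {
  schema <- match.arg(schema)
  cfg <- switch(schema,
    desc = list(root = "DescriptorRecordSet", rec = "DescriptorRecord",
                name = "DescriptorName", syn_tree = "ConceptList"),
    pa = list(root = "PharmacologicalActionSet", rec = "PharmacologicalAction",
              name = "DescriptorName",
              syn_tree = "PharmacologicalActionSubstanceList"),
    qual = list(root = "QualifierRecordSet", rec = "QualifierRecord",
                name = "QualifierName", syn_tree = "ConceptList"),
    suppl = list(root = "SupplementalRecordSet", rec = "SupplementalRecord",
                 name = "SupplementalRecordName", syn_tree = "ConceptList")
  )
  root <- xml2::xml_new_root(cfg$root)
  for (nm in names) {
    rec <- xml2::xml_add_child(root, cfg$rec)
    nnode <- xml2::xml_add_child(rec, cfg$name)
    xml2::xml_add_child(nnode, "String", nm)
  }
  if (length(synonyms)) {
    rec <- xml2::xml_add_child(root, cfg$rec)
    nnode <- xml2::xml_add_child(rec, cfg$name)
    xml2::xml_add_child(nnode, "String", names[1])
    tree <- xml2::xml_add_child(rec, cfg$syn_tree)
    for (s in synonyms) {
      c1 <- xml2::xml_add_child(tree, "Concept")
      t1 <- xml2::xml_add_child(c1, "TermList")
      t2 <- xml2::xml_add_child(t1, "Term")
      xml2::xml_add_child(t2, "String", s)
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read single-line topics
#'
#' One topic per line: `topic_id<TAB>query text` (or the id separated by
#' the first run of whitespace).
#'
#' @param path Topics file path.
#' @return Data frame `topic`, `text`.
#' @export
read_topics <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexpr("^\\S+", lines))
  txt <- trimws(sub("^\\S+\\s*", "", lines))
  data.frame(topic = m, text = txt, stringsAsFactors = FALSE)
}

#' @rdname read_topics
#' @param topics Data frame `topic`, `text`.
#' @export
write_topics <- function(topics, path) {
  writeLines(paste0(topics$topic, "\t", topics$text), path,
             useBytes = TRUE)
  invisible(path)
}

#' Materialize a full fixture bundle on disk
#'
#' Writes everything a pipeline run needs: `collection.xml`, a MeSH
#' vocabulary fixture covering the collection's gene-symbol tokens,
#' embedding vector files for both spaces (clusters seeded with the topic
#' theme words), `topics.txt`, full and subsampled qrels, and the truth
#' table.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths plus the in-memory fixture
#'   objects (`fixture`, `qrels`, `spaces`).
#' @export
make_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_collection(spec, path = file.path(dir, "collection.xml"))
  qr <- make_qrels(spec, fx)
  write_qrels(qr$full, file.path(dir, "qrels-full.txt"))
  write_qrels(qr$sampled, file.path(dir, "qrels-sampled.txt"))
  write_topics(fx$topics[, c("topic", "text")],
               file.path(dir, "topics.txt"))
  make_mesh_fixture(file.path(dir, "mesh-desc-synthetic.xml"),
                    names = c("Melanoma", "Abdomen, Acute"),
                    synonyms = fx$mesh_symbols, schema = "desc")
  # embedding clusters seeded with the theme words plus related filler
  set.seed(spec$seed + 4000L)
  theme_words <- unlist(fx$themes, use.names = FALSE)
  extras <- sample(setdiff(fx$filler, theme_words),
                   (spec$cluster_size - 1) * length(theme_words))
  clusters <- lapply(seq_along(theme_words), function(i) {
    c(theme_words[i],
      extras[((i - 1) * (spec$cluster_size - 1) + 1):
               (i * (spec$cluster_size - 1))])
  })
  sp_coll <- make_embeddings(spec, clusters = clusters,
                             source = "collection",
                             path = file.path(dir, "vectors-collection.txt"))
  sp_pub <- make_embeddings(spec, clusters = clusters, source = "pubmed",
                            path = file.path(dir, "vectors-pubmed.txt"))
  utils::write.table(fx$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(collection = file.path(dir, "collection.xml"),
       qrels_full = file.path(dir, "qrels-full.txt"),
       qrels_sampled = file.path(dir, "qrels-sampled.txt"),
       topics = file.path(dir, "topics.txt"),
       mesh = file.path(dir, "mesh-desc-synthetic.xml"),
       vectors_collection = file.path(dir, "vectors-collection.txt"),
       vectors_pubmed = file.path(dir, "vectors-pubmed.txt"),
       truth = file.path(dir, "truth.tsv"),
       fixture = fx, qrels = qr,
       spaces = list(collection = sp_coll, pubmed = sp_pub))
}
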