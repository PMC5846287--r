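#' Configuration of an end-to-end retrieval run
#'
#' Collects every input path and parameter of one reproducible run:
#' lexicon build, normalization, filtering, indexing, expansion, retrieval,
#' PRF and evaluation. All referenced paths must exist when the config is
#' built; the effective config is serialized next to the outputs.
#'
#' @param collection Path to the collection XML.
#' @param topics Path to a topics file ([read_topics()]) or a data frame
#'   with `topic`, `text`.
#' @param out_dir Output directory (created if needed).
#' @param qrels Optional qrels path or [sampled_qrels()]; enables the
#'   evaluation stage.
#' @param mappings Optional YAML path of category mappings (default: the
#'   built-in mappings).
#' @param mesh_files Character vector of MeSH XML paths for the lexicon
#'   build.
#' @param mesh_cache Optional one-word-per-line cached MeSH word list
#'   (used instead of `mesh_files` when given).
#' @param english_words Optional word-list path (default: packaged list).
#' @param vectors_pubmed,vectors_collection Optional word2vec text files;
#'   either enables embedding expansion.
#' @param model Weighting-model id (default `"LGD"`).
#' @param params [model_params()].
#' @param expansion [expansion_config()], used when vector files are given.
#' @param prf [prf_params()] or `NULL` to disable feedback.
#' @param cutoff Rank depth of retrieval (default 1000).
#' @param tag Run tag (default: model id).
#' @param seed Integer recorded in the provenance (the pipeline itself is
#'   deterministic; the seed matters when fixture generation is scripted
#'   around it).
#' @return A `run_config` list.
#' @export
run_config <- function(collection, topics, out_dir, qrels = NULL,
                       mappings = NULL, mesh_files = character(0),
                       mesh_cache = NULL, english_words = NULL,
                       vectors_pubmed = NULL, vectors_collection = NULL,
                       model = "LGD", params = model_params(),
                       expansion = expansion_config(), prf = prf_params(),
                       cutoff = 1000L, tag = NULL, seed = 1L) {
  paths <- c(collection = collection,
             if (is.character(topics)) c(topics = topics),
             if (is.character(qrels)) c(qrels = qrels),
             if (!is.null(mappings)) c(mappings = mappings),
             if (length(mesh_files)) stats::setNames(mesh_files,
               paste0("mesh", seq_along(mesh_files))),
             if (!is.null(mesh_cache)) c(mesh_cache = mesh_cache),
             if (!is.null(english_words)) c(english_words = english_words),
             if (!is.null(vectors_pubmed)) c(vectors_pubmed = vectors_pubmed),
             if (!is.null(vectors_collection))
               c(vectors_collection = vectors_collection))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(collection = collection, topics = topics, out_dir = out_dir,
         qrels = qrels, mappings = mappings, mesh_files = mesh_files,
         mesh_cache = mesh_cache, english_words = english_words,
         vectors_pubmed = vectors_pubmed,
         vectors_collection = vectors_collection,
         model = .canon_model(model), params = params,
         expansion = expansion, prf = prf, cutoff = as.integer(cutoff),
         tag = tag %||% .canon_model(model), seed = as.integer(seed)),
    class = "run_config"
  )
}

.stage <- function(name, expr, verbose) {
  .msg("[stage] ", name, verbose = verbose)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Execute the full retrieval pipeline
#'
#' Runs, in order: lexicon build, collection parsing, category
#' normalization, informativeness filtering, corpus writing, indexing,
#' query cleaning, embedding expansion (when vector files are configured),
#' first-pass retrieval, pseudo-relevance feedback (when configured),
#' final retrieval, run-file writing and evaluation (when qrels are
#' configured). The run is deterministic: the same config over the same
#' inputs produces byte-identical outputs, and a provenance table of MD5
#' checksums for all inputs and outputs is written alongside them. On any
#' stage failure the partial outputs are removed.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress and counts.
#' @return List with `run_file`, `report` (an `eval_report` or `NULL`),
#'   `report_file`, `corpus_file`, `provenance_file`, `config_file`,
#'   `counts` (named per-stage counts) and `queries` (the final weighted
#'   queries).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tagfile <- function(ext) file.path(config$out_dir,
                                     paste0(config$tag, ext))
  outputs <- c(run = tagfile(".run"), corpus = tagfile("-corpus.xml"),
               report = tagfile("-report.tsv"),
               config = tagfile("-config.yaml"),
               provenance = tagfile("-provenance.tsv"))
  on_fail <- function() unlink(outputs[file.exists(outputs)])
  withCallingHandlers({
    lexicon <- .stage("build-lexicon", {
      eng <- if (is.null(config$english_words)) default_english_words() else
        read_wordlist(config$english_words)
      mesh <- if (!is.null(config$mesh_cache)) {
        read_wordlist(config$mesh_cache)
      } else if (length(config$mesh_files)) {
        build_mesh_lexicon(config$mesh_files)
      } else character(0)
      term_lexicon(eng, mesh,
                   manifest = c(english = config$english_words %||%
                                  "packaged",
                                mesh = config$mesh_cache %||%
                                  paste(config$mesh_files,
                                        collapse = ";")))
    }, verbose)

    docs <- .stage("parse-collection",
                   parse_collection(config$collection, quiet = TRUE),
                   verbose)
    mappings <- if (is.null(config$mappings)) default_category_mappings()
      else read_category_mappings(config$mappings)
    records <- .stage("normalize", normalize_collection(docs, mappings),
                      verbose)
    decisions <- .stage("filter",
                        filter_collection(records, lexicon,
                                          verbose = verbose), verbose)
    .stage("write-corpus",
           write_indexable_corpus(records, decisions, outputs["corpus"]),
           verbose)
    index <- .stage("index", {
      corpus <- read_indexable_corpus(outputs["corpus"])
      build_index(corpus)
    }, verbose)

    topics <- if (is.character(config$topics)) read_topics(config$topics)
      else config$topics
    spaces <- .stage("load-vectors", {
      sp <- list()
      if (!is.null(config$vectors_pubmed)) {
        sp <- c(sp, list(read_word2vec(config$vectors_pubmed,
                                       source = "pubmed")))
      }
      if (!is.null(config$vectors_collection)) {
        sp <- c(sp, list(read_word2vec(config$vectors_collection,
                                       source = "collection")))
      }
      sp
    }, verbose)

    queries <- list()
    rankings <- list()
    n_expanded <- 0L
    for (i in seq_len(nrow(topics))) {
      tp <- topics$topic[i]
      terms <- .stage(paste0("clean-query:", tp),
                      suppressWarnings(clean_query(topics$text[i])),
                      verbose = FALSE)
      if (!length(terms)) {
        .msg("topic ", tp, ": empty after cleaning; empty ranking",
             verbose = verbose)
        rankings[[tp]] <- suppressWarnings(
          search(character(0), index, model = config$model, topic = tp,
                 tag = config$tag))
        next
      }
      q <- if (length(spaces)) {
        expand_with_embeddings(terms, spaces, config$expansion)
      } else {
        weighted_query(terms)
      }
      if (!is.null(config$prf)) {
        first <- search(q, index, model = config$model,
                        params = config$params, cutoff = config$cutoff,
                        topic = tp, tag = config$tag)
        if (nrow(first)) {
          q <- prf_expand(q, index, first, config$prf)
        }
      }
      n_expanded <- n_expanded + sum(q$source != "original")
      queries[[tp]] <- q
      rankings[[tp]] <- search(q, index, model = config$model,
                               params = config$params,
                               cutoff = config$cutoff, topic = tp,
                               tag = config$tag)
    }
    .stage("write-run", write_run(rankings, outputs["run"],
                                  tag = config$tag), verbose)

    report <- NULL
    if (!is.null(config$qrels)) {
      report <- .stage("evaluate", {
        qr <- if (is.character(config$qrels)) parse_qrels(config$qrels)
          else config$qrels
        rep <- evaluate_run(rankings, qr)
        write_eval_report(rep, outputs["report"])
        rep
      }, verbose)
    }

    .stage("provenance", {
      cfg <- config
      cfg$params <- unclass(cfg$params)
      cfg$expansion <- if (!is.null(cfg$expansion)) {
        e <- unclass(cfg$expansion)
        e$thresholds <- as.list(e$thresholds)
        e$weights <- as.list(e$weights)
        e
      }
      cfg$prf <- if (!is.null(cfg$prf)) unclass(cfg$prf)
      yaml::write_yaml(lapply(unclass(cfg), function(x)
        if (is.null(x)) NULL else x), outputs["config"])
      files <- c(collection = config$collection,
                 outputs[c("corpus", "run")],
                 if (!is.null(report)) outputs["report"])
      sums <- tools::md5sum(unname(files))
      utils::write.table(
        data.frame(file = basename(names(sums)), md5 = unname(sums)),
        outputs["provenance"], sep = "\t", quote = FALSE,
        row.names = FALSE)
    }, verbose)

    counts <- c(docs_parsed = length(docs),
                docs_skipped = attr(docs, "n_skipped"),
                json_errors = attr(docs, "n_json_errors"),
                docs_dropped = sum(decisions$drop),
                docs_indexed = index$N,
                terms_indexed = nrow(index$term_stats),
                expansion_terms = n_expanded,
                topics_run = nrow(topics))
    .msg("pipeline done: ", paste(names(counts), counts, sep = "=",
                                  collapse = " "), verbose = verbose)
    list(run_file = unname(outputs["run"]), report = report,
         report_file = if (!is.null(report)) unname(outputs["report"]),
         corpus_file = unname(outputs["corpus"]),
         provenance_file = unname(outputs["provenance"]),
         config_file = unname(outputs["config"]), counts = counts,
         queries = queries, rankings = rankings, index = index,
         decisions = decisions)
  }, error = function(e) on_fail())
}

#' Compare evaluation reports across models
#'
#' Lays several runs' mean measures out as a models-by-measures grid and
#' flags each column's maximum, mirroring the usual baseline-comparison
#' tables of retrieval papers.
#'
#' @param reports Named list of `eval_report`s (names become row labels).
#' @return A `run_comparison` data frame (`model` column plus one column
#'   per measure) with attribute `is_max` (logical matrix marking
#'   per-column maxima).
#' @export
compare_runs <- function(reports) {
  stopifnot(length(reports) >= 2L, !is.null(names(reports)))
  topic_sets <- lapply(reports, function(r) sort(r$per_topic$topic))
  ref <- topic_sets[[1]]
  for (i in seq_along(topic_sets)[-1]) {
    if (!identical(topic_sets[[i]], ref)) {
      sd <- union(setdiff(topic_sets[[i]], ref),
                  setdiff(ref, topic_sets[[i]]))
      stop("reports cover different topics; symmetric difference: ",
           paste(sd, collapse = ", "), call. = FALSE)
    }
  }
  vals <- do.call(rbind, lapply(reports, function(r) r$means))
  df <- data.frame(model = names(reports), vals, stringsAsFactors = FALSE,
                   row.names = NULL)
  is_max <- apply(vals, 2, function(col) col == max(col))
  if (is.null(dim(is_max))) is_max <- matrix(is_max, nrow = 1)
  dimnames(is_max) <- list(names(reports), colnames(vals))
  attr(df, "is_max") <- is_max
  class(df) <- c("run_comparison", "data.frame")
  df
}

#' @export
print.run_comparison <- function(x, digits = 4, ...) {
  is_max <- attr(x, "is_max")
  out <- x
  for (cn in colnames(is_max)) {
    out[[cn]] <- paste0(formatC(x[[cn]], digits = digits, format = "f"),
                        ifelse(is_max[, cn], " *", "  "))
  }
  print.data.frame(out, row.names = FALSE)
  cat("(* = column maximum)\n")
  invisible(x)
}
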