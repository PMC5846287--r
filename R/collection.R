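#' Parse a dataset-metadata XML collection
#'
#' Reads the TREC-style XML dialect used by dataset-discovery benchmarks: a
#' sequence of `<DOC>` elements, each carrying `<DOCNO>` (identifier),
#' `<TITLE>` (free text, possibly absent), `<REPOSITORY>` (source repository
#' token) and `<METADATA>` (repository-specific JSON). A bare sequence of
#' `DOC` elements without a root element is accepted and wrapped internally.
#'
#' Records lacking a (non-empty) `DOCNO` are skipped and counted rather than
#' aborting the parse; `METADATA` payloads that are not valid JSON yield an
#' empty metadata tree plus a counted warning. Truncated or malformed XML is a
#' fatal error (reported with the offending location by the XML parser).
#'
#' @param x Path to an XML file, or a length-1 character string starting with
#'   `<` holding the XML itself.
#' @param quiet Suppress per-record warnings (counts are still recorded).
#' @return A list of `dataset_document` objects (fields `docno`, `title`,
#'   `repository`, `metadata`), classed `dataset_collection`, with attributes
#'   `n_skipped` (records dropped for missing docno) and `n_json_errors`.
#' @export
parse_collection <- function(x, quiet = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (grepl("^\\s*<", x)) x else {
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  doc <- tryCatch(
    xml2::read_xml(txt, encoding = "UTF-8"),
    error = function(e) {
      # the dialect allows a rootless stream of DOC elements
      tryCatch(
        xml2::read_xml(paste0("<collection>", txt, "</collection>"),
                       encoding = "UTF-8"),
        error = function(e2) stop("fatal XML parse error: ",
                                  conditionMessage(e), call. = FALSE)
      )
    }
  )
  nodes <- xml2::xml_find_all(doc, "//DOC")
  n_skipped <- 0L
  n_json <- 0L
  out <- vector("list", length(nodes))
  kept <- 0L
  for (nd in nodes) {
    docno <- .xml_child_text(nd, "DOCNO")
    if (is.na(docno) || !nzchar(trimws(docno))) {
      n_skipped <- n_skipped + 1L
      if (!quiet) warning("DOC without DOCNO skipped", call. = FALSE)
      next
    }
    docno <- trimws(docno)
    title <- .xml_child_text(nd, "TITLE")
    if (is.na(title)) title <- ""
    repo <- .xml_child_text(nd, "REPOSITORY")
    repo <- if (is.na(repo) || !nzchar(trimws(repo))) "unknown" else trimws(repo)
    meta_txt <- .xml_child_text(nd, "METADATA")
    metadata <- list()
    if (!is.na(meta_txt) && nzchar(trimws(meta_txt))) {
      metadata <- tryCatch(
        jsonlite::fromJSON(meta_txt, simplifyVector = FALSE),
        error = function(e) {
          n_json <<- n_json + 1L
          if (!quiet) warning("invalid METADATA JSON in doc ", docno,
                              "; metadata dropped", call. = FALSE)
          list()
        }
      )
      if (!is.list(metadata)) metadata <- list(value = metadata)
      if (length(metadata) == 0L) metadata <- list()
    }
    kept <- kept + 1L
    out[[kept]] <- structure(
      list(docno = docno, title = trimws(title), repository = repo,
           metadata = metadata),
      class = "dataset_document"
    )
  }
  out <- out[seq_len(kept)]
  ids <- vapply(out, `[[`, "", "docno")
  if (anyDuplicated(ids)) {
    stop("duplicate DOCNO in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(out, class = "dataset_collection",
            n_skipped = n_skipped, n_json_errors = n_json)
}

.xml_child_text <- function(node, name) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing")) return(NA_character_)
  xml2::xml_text(ch)
}

#' Write documents back to the collection XML dialect
#'
#' Inverse of [parse_collection()]: serializes `dataset_document` objects as
#' `<DOC>` elements under a `<collection>` root, with metadata re-encoded as
#' JSON inside `<METADATA>`. `parse_collection(write_collection(docs))`
#' reproduces `docs`.
#'
#' @param docs A `dataset_collection` or list of `dataset_document`s.
#' @param path Output file path, or `NULL` to return the XML as a string.
#' @return `path` invisibly, or the XML string when `path` is `NULL`.
#' @export
write_collection <- function(docs, path = NULL) {
  root <- xml2::xml_new_root("collection")
  for (d in docs) {
    nd <- xml2::xml_add_child(root, "DOC")
    xml2::xml_add_child(nd, "DOCNO", d$docno)
    xml2::xml_add_child(nd, "TITLE", d$title)
    xml2::xml_add_child(nd, "REPOSITORY", d$repository)
    meta <- if (length(d$metadata)) {
      as.character(jsonlite::toJSON(d$metadata, auto_unbox = TRUE))
    } else ""
    xml2::xml_add_child(nd, "METADATA", meta)
  }
  if (is.null(path)) return(as.character(root))
  xml2::write_xml(root, path)
  invisible(path)
}

#' Flatten a parsed JSON metadata tree to dotted key paths
#'
#' Named members contribute their name to the path; unnamed (array) members
#' contribute their 1-based position. Leaf values are coerced to character.
#'
#' @param x Nested list from JSON parsing.
#' @return Named character vector of leaf values keyed by dotted paths.
#' @export
flatten_metadata <- function(x) {
  out <- character(0)
  rec <- function(node, path) {
    if (is.list(node)) {
      if (length(node) == 0L) return(invisible(NULL))
      nms <- names(node)
      for (i in seq_along(node)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        rec(node[[i]], if (nzchar(path)) paste(path, key, sep = ".") else key)
      }
    } else if (!is.null(node) && length(node) > 0L) {
      val <- paste(as.character(node), collapse = " ")
      out[[path]] <<- val
    }
    invisible(NULL)
  }
  rec(x, "")
  out
}

# suffix matching of flattened keys against mapping names: dots/underscores
# are dropped and case ignored, since mapping names come from flattened
# staging-column conventions rather than literal JSON paths
.norm_key <- function(k) tolower(gsub("[._]", "", k))

.match_suffix <- function(flat_keys, map_key) {
  nk <- .norm_key(flat_keys)
  mk <- .norm_key(map_key)
  endsWith(nk, mk)
}

#' Default repository-to-category mappings
#'
#' Returns the built-in mapping from repository-specific metadata keys to the
#' three text categories (title, keywords, description) for the twenty
#' repositories found in dataset-discovery benchmark collections. Repositories
#' not listed fall back to `title -> "title"`, `description -> "description"`.
#'
#' Each entry is a list with `title_keys`, `keyword_keys`, `description_keys`:
#' ordered vectors of key names matched case-insensitively as suffixes of the
#' flattened metadata key paths (see [flatten_metadata()]). The special key
#' `"title"` also matches the document's `<TITLE>` tag.
#'
#' @return Named list of category mappings, one per repository.
#' @seealso [normalize_record()], [read_category_mappings()]
#' @export
default_category_mappings <- function() {
  m <- function(title = "title", keywords = character(0),
                description = character(0)) {
    list(title_keys = title, keyword_keys = keywords,
         description_keys = description)
  }
  list(
    arrayexpress   = m(description = "description"),
    bioproject     = m(keywords = c("dataItemkeywords", "organismtargetspecies"),
                       description = "dataItemdescription"),
    cia            = m(description = c("anatomicalPartname", "diseasename",
                                       "organismname", "organismscientificname")),
    clinicaltrials = m(keywords = "keyword",
                       description = c("criteria", "StudyGroupdescription",
                                       "Diseasename", "Treatmentdescription",
                                       "Treatmentagent", "Datasetdescription")),
    ctn            = m(keywords = "datasetkeywords",
                       description = c("datasetdescription",
                                       "organismscientificName", "organismname")),
    cvrg           = m(description = "datasetdescription"),
    dataverse      = m(description = c("publicationdescription",
                                       "datasetdescription")),
    dryad          = m(keywords = "datasetkeywords",
                       description = "datasetdescription"),
    gemma          = m(description = c("dataItemdescription",
                                       "organismcommonName")),
    geo            = m(description = c("dataItemsource_name", "dataItemorganism",
                                       "dataItemdescription")),
    mpd            = m(description = c("datasetdescription",
                                       "organismscientificName", "organismname")),
    neuromorpho    = m(description = c("anatomicalPartname", "cellname",
                                       "organismscientificName", "organismname")),
    nursadatasets  = m(keywords = "datasetkeywords",
                       description = c("datasetdescription", "organismname")),
    openfmri       = m(description = "datasetdescription"),
    pdb            = m(keywords = "dataItemkeywords",
                       description = c("dataItemdescription",
                                       "organismsourcescientificName",
                                       "organismhostscientificName", "genename")),
    peptideatlas   = m(description = c("datasetdescription",
                                       "treatmentdescription")),
    phenodisco     = m(description = c("inexclude", "desc", "disease",
                                       "history")),
    physiobank     = m(description = "datasetdescription"),
    proteomexchange = m(keywords = "keywords", description = "organismname"),
    yped           = m(description = c("datasetdescription", "organismname"))
  )
}

.fallback_mapping <- function() {
  list(title_keys = "title", keyword_keys = character(0),
       description_keys = "description")
}

#' Read / write category mappings as YAML
#'
#' The on-disk format mirrors [default_category_mappings()]: a map from
#' repository name to `title_keys` / `keyword_keys` / `description_keys`
#' sequences.
#'
#' @param path YAML file path.
#' @return For `read_category_mappings`, a named list of mappings.
#' @export
read_category_mappings <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e) {
    list(
      title_keys = as.character(e$title_keys %||% character(0)),
      keyword_keys = as.character(e$keyword_keys %||% character(0)),
      description_keys = as.character(e$description_keys %||% character(0))
    )
  })
}

#' @rdname read_category_mappings
#' @param mappings Named list of mappings.
#' @export
write_category_mappings <- function(mappings, path) {
  yaml::write_yaml(mappings, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.squash_ws <- function(x) trimws(gsub("\\s+", " ", x))

#' Normalize a document into title/keywords/description text
#'
#' Applies a category mapping to a parsed document: each category's text is
#' the space-joined concatenation, in mapping order, of the values of every
#' flattened metadata key that matches one of the category's key names
#' (case-insensitive suffix match). The document's `<TITLE>` tag participates
#' under the key name `"title"`. Missing keys contribute nothing; a category
#' with no matched value is the empty string.
#'
#' @param doc A `dataset_document`.
#' @param mapping A single category mapping (see
#'   [default_category_mappings()]); when `NULL` the mapping for
#'   `doc$repository` is looked up in `mappings`, falling back to the
#'   title/description default for unknown repositories.
#' @param mappings Named list of mappings used for the lookup.
#' @return A `normalized_record`: list with `docno`, `repository`,
#'   `title_text`, `keywords_text`, `description_text`.
#' @export
normalize_record <- function(doc, mapping = NULL,
                             mappings = default_category_mappings()) {
  if (is.null(mapping)) {
    mapping <- mappings[[doc$repository]] %||% .fallback_mapping()
  }
  pool <- flatten_metadata(doc$metadata)
  if (nzchar(doc$title) && !any(.match_suffix(names(pool), "title"))) {
    pool <- c(stats::setNames(doc$title, "title"), pool)
  }
  cat_text <- function(keys) {
    vals <- character(0)
    for (k in keys) {
      if (identical(tolower(k), "title") && nzchar(doc$title)) {
        vals <- c(vals, doc$title)
        extra <- pool[.match_suffix(names(pool), k) & names(pool) != "title"]
        vals <- c(vals, unname(extra))
      } else {
        vals <- c(vals, unname(pool[.match_suffix(names(pool), k)]))
      }
    }
    .squash_ws(paste(vals[nzchar(vals)], collapse = " "))
  }
  structure(
    list(docno = doc$docno, repository = doc$repository,
         title_text = cat_text(mapping$title_keys),
         keywords_text = cat_text(mapping$keyword_keys),
         description_text = cat_text(mapping$description_keys)),
    class = "normalized_record"
  )
}

#' Normalize every document in a collection
#'
#' @param docs A `dataset_collection` (from [parse_collection()]).
#' @param mappings Named list of category mappings.
#' @return List of `normalized_record`s.
#' @export
normalize_collection <- function(docs, mappings = default_category_mappings()) {
  lapply(docs, normalize_record, mappings = mappings)
}

#' Write the filtered, indexable corpus
#'
#' Emits one `<DOC>` (with `<DOCNO>` and `<TEXT>`) per record that has at
#' least one category kept by the informativeness filter; the kept category
#' texts are concatenated with single spaces. Records with no kept category
#' are omitted entirely.
#'
#' @param records List of `normalized_record`s.
#' @param decisions Data frame from [filter_collection()] with columns
#'   `docno`, `keep_title`, `keep_keywords`, `keep_description`.
#' @param path Output path, or `NULL` to return the XML string.
#' @return `path` invisibly (or the XML string), with attribute `n_written`.
#' @export
write_indexable_corpus <- function(records, decisions, path = NULL) {
  stopifnot(all(c("docno", "keep_title", "keep_keywords",
                  "keep_description") %in% names(decisions)))
  dec <- decisions[match(vapply(records, `[[`, "", "docno"), decisions$docno), ]
  root <- xml2::xml_new_root("collection")
  n <- 0L
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.na(dec$docno[i])) next
    if (!(isTRUE(dec$keep_title[i]) || isTRUE(dec$keep_keywords[i]) ||
          isTRUE(dec$keep_description[i]))) next
    parts <- c(if (isTRUE(dec$keep_title[i])) r$title_text,
               if (isTRUE(dec$keep_keywords[i])) r$keywords_text,
               if (isTRUE(dec$keep_description[i])) r$description_text)
    parts <- parts[nzchar(parts)]
    nd <- xml2::xml_add_child(root, "DOC")
    xml2::xml_add_child(nd, "DOCNO", r$docno)
    xml2::xml_add_child(nd, "TEXT", paste(parts, collapse = " "))
    n <- n + 1L
  }
  if (is.null(path)) {
    out <- as.character(root)
    attr(out, "n_written") <- n
    return(out)
  }
  xml2::write_xml(root, path)
  invisible(structure(path, n_written = n))
}

#' Read an indexable corpus written by [write_indexable_corpus()]
#'
#' @param x Path or XML string.
#' @return Data frame with columns `docno` and `text`.
#' @export
read_indexable_corpus <- function(x) {
  txt <- if (grepl("^\\s*<", x)) x else {
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }
  doc <- xml2::read_xml(txt, encoding = "UTF-8")
  nodes <- xml2::xml_find_all(doc, "//DOC")
  data.frame(
    docno = vapply(nodes, function(n) trimws(.xml_child_text(n, "DOCNO")), ""),
    text = vapply(nodes, function(n) {
      t <- .xml_child_text(n, "TEXT"); if (is.na(t)) "" else t
    }, ""),
    stringsAsFactors = FALSE
  )
}
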