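test_that("parse_collection maps the four tags and tolerates gaps", {
  docs <- suppressWarnings(parse_collection(sample_collection_xml()))
  expect_length(docs, 3L)
  d1 <- docs[[1]]
  expect_identical(d1$docno, "d1")
  expect_identical(d1$title, "t")
  expect_identical(d1$repository, "geo")
  expect_identical(d1$metadata, list())
  # missing TITLE tag: document retained with empty title
  expect_identical(docs[[2]]$title, "")
  expect_identical(docs[[2]]$metadata$datasetdescription, "liver samples")
  # malformed METADATA JSON: retained with empty metadata, counted
  expect_identical(docs[[3]]$metadata, list())
  expect_identical(attr(docs, "n_json_errors"), 1L)
})

test_that("records without DOCNO are skipped and counted, not fatal", {
  xml <- paste0(
    "<collection>",
    "<DOC><TITLE>orphan</TITLE><REPOSITORY>geo</REPOSITORY>",
    "<METADATA>{}</METADATA></DOC>",
    "<DOC><DOCNO>ok</DOCNO><TITLE>x</TITLE><REPOSITORY>geo</REPOSITORY>",
    "<METADATA>{}</METADATA></DOC></collection>")
  docs <- suppressWarnings(parse_collection(xml))
  expect_length(docs, 1L)
  expect_identical(attr(docs, "n_skipped"), 1L)
  # count conservation: in = out + skipped
  expect_identical(length(docs) + attr(docs, "n_skipped"), 2L)
})

test_that("truncated XML and duplicate docnos are fatal", {
  expect_error(parse_collection("<collection><DOC><DOCNO>a</DOCNO>"),
               "parse error")
  dup <- paste0("<collection>",
                "<DOC><DOCNO>a</DOCNO><TITLE>1</TITLE>",
                "<REPOSITORY>geo</REPOSITORY><METADATA>{}</METADATA></DOC>",
                "<DOC><DOCNO>a</DOCNO><TITLE>2</TITLE>",
                "<REPOSITORY>geo</REPOSITORY><METADATA>{}</METADATA></DOC>",
                "</collection>")
  expect_error(parse_collection(dup), "duplicate DOCNO")
})

test_that("write_collection round-trips: parse(write(parse(x))) = parse(x)", {
  docs <- suppressWarnings(parse_collection(sample_collection_xml(),
                                            quiet = TRUE))
  docs2 <- parse_collection(write_collection(docs))
  expect_length(docs2, length(docs))
  for (i in seq_along(docs)) {
    expect_identical(unclass(docs2[[i]]), unclass(docs[[i]]))
  }
  # and idempotently so
  docs3 <- parse_collection(write_collection(docs2))
  expect_identical(lapply(docs3, unclass), lapply(docs2, unclass))
})

test_that("flatten_metadata dot-joins nested keys and indexes arrays", {
  x <- list(a = list(b = "1", c = list("x", "y")), d = "z")
  fl <- flatten_metadata(x)
  expect_identical(fl[["a.b"]], "1")
  expect_identical(fl[["a.c.1"]], "x")
  expect_identical(fl[["a.c.2"]], "y")
  expect_identical(fl[["d"]], "z")
  expect_identical(flatten_metadata(list()), character(0))
})

test_that("normalize_record concatenates mapped keys in mapping order", {
  doc <- structure(list(
    docno = "b1", title = "Study title", repository = "bioproject",
    metadata = list(dataItemkeywords = "x", organismtargetspecies = "y",
                    dataItemdescription = "long text")),
    class = "dataset_document")
  rec <- normalize_record(doc)
  expect_identical(rec$title_text, "Study title")
  expect_true(grepl("\\bx\\b", rec$keywords_text))
  expect_true(grepl("\\by\\b", rec$keywords_text))
  expect_identical(rec$keywords_text, "x y")  # mapping order
  expect_identical(rec$description_text, "long text")
})

test_that("normalize handles missing keys, unknown repos and case", {
  # no mapped keys at all: all categories empty
  doc <- structure(list(docno = "e1", title = "", repository = "geo",
                        metadata = list(unrelated = "v")),
                   class = "dataset_document")
  rec <- normalize_record(doc)
  expect_identical(rec$title_text, "")
  expect_identical(rec$keywords_text, "")
  expect_identical(rec$description_text, "")
  # dryad doc with title only (the degenerate chr19 shape)
  doc2 <- structure(list(docno = "104242", title = "chr19",
                         repository = "dryad", metadata = list()),
                    class = "dataset_document")
  rec2 <- normalize_record(doc2)
  expect_identical(rec2$title_text, "chr19")
  expect_identical(rec2$keywords_text, "")
  expect_identical(rec2$description_text, "")
  # unknown repository falls back to title/description keys
  doc3 <- structure(list(docno = "u1", title = "T", repository = "novelrepo",
                         metadata = list(description = "D")),
                    class = "dataset_document")
  rec3 <- normalize_record(doc3)
  expect_identical(rec3$title_text, "T")
  expect_identical(rec3$description_text, "D")
  # suffix matching is case-insensitive and dot-insensitive
  doc4 <- structure(list(docno = "c1", title = "", repository = "dryad",
                         metadata = list(DataSet.Description = "dd")),
                    class = "dataset_document")
  expect_identical(normalize_record(doc4)$description_text, "dd")
})

test_that("normalization is deterministic and order-stable", {
  doc <- structure(list(
    docno = "m1", title = "t", repository = "mpd",
    metadata = list(datasetdescription = "a", organismscientificName = "b",
                    organismname = "c")),
    class = "dataset_document")
  r1 <- normalize_record(doc)
  expect_identical(r1$description_text, "a b c")
  expect_identical(normalize_record(doc), r1)
})

test_that("write_indexable_corpus keeps only approved fields and records", {
  recs <- list(
    structure(list(docno = "k1", repository = "geo", title_text = "kept title",
                   keywords_text = "kw", description_text = "desc"),
              class = "normalized_record"),
    structure(list(docno = "k2", repository = "geo", title_text = "gone",
                   keywords_text = "", description_text = ""),
              class = "normalized_record"))
  dec <- data.frame(docno = c("k1", "k2"),
                    keep_title = c(TRUE, FALSE),
                    keep_keywords = c(FALSE, FALSE),
                    keep_description = c(FALSE, FALSE))
  out <- read_indexable_corpus(write_indexable_corpus(recs, dec))
  expect_identical(out$docno, "k1")
  expect_identical(out$text, "kept title")
  # empty input produces a well-formed empty collection
  empty <- read_indexable_corpus(
    write_indexable_corpus(list(), dec[0, ]))
  expect_identical(nrow(empty), 0L)
})

test_that("category mappings survive a YAML round-trip", {
  maps <- default_category_mappings()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_category_mappings(maps, path)
  maps2 <- read_category_mappings(path)
  expect_identical(names(maps2), names(maps))
  expect_identical(maps2$bioproject$keyword_keys,
                   maps$bioproject$keyword_keys)
  expect_identical(maps2$pdb$description_keys, maps$pdb$description_keys)
})
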