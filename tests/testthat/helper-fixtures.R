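# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is downloaded or stored in binary form.

# a tiny lexicon: a handful of English words plus gene-symbol MeSH words
tiny_lexicon <- function(extra_mesh = character(0)) {
  term_lexicon(
    english_words = c("acute", "liver", "cancer", "mouse", "gene",
                      "expression", "profile", "melanoma", "study",
                      "samples", "of", "in", "human"),
    mesh_words = c("mip-2", "cd69", "ldlr", "abdomen", extra_mesh)
  )
}

# hand-written collection XML exercising the dialect's corner cases
sample_collection_xml <- function() {
  paste0(
    "<collection>",
    "<DOC><DOCNO>d1</DOCNO><TITLE>t</TITLE><REPOSITORY>geo</REPOSITORY>",
    "<METADATA>{}</METADATA></DOC>",
    "<DOC><DOCNO>d2</DOCNO><REPOSITORY>dryad</REPOSITORY>",
    "<METADATA>{\"datasetdescription\": \"liver samples\"}</METADATA></DOC>",
    "<DOC><DOCNO>d3</DOCNO><TITLE>bad json</TITLE>",
    "<REPOSITORY>geo</REPOSITORY><METADATA>{not json</METADATA></DOC>",
    "</collection>"
  )
}

# the six verbatim degenerate records that the filter must reject
degenerate_records <- function() {
  mk <- function(docno, repo, title, desc) {
    structure(list(docno = docno, repository = repo,
                   title_text = title, keywords_text = "",
                   description_text = desc),
              class = "normalized_record")
  }
  list(
    mk("104242", "dryad", "chr19", ""),
    mk("108196", "dryad", "Chr8", ""),
    mk("124757", "bioproject", "Sobemovirus", ""),
    mk("151909", "bioproject", "Alphaflexiviridae", ""),
    mk("500000", "geo", "A375R_RPL10a_vivo__Ronly_vem10d_rep2", "melanoma"),
    mk("500002", "geo", "A375_vitro_vehicle_rep3", "melanoma")
  )
}

# small deterministic corpus for ranking tests: returns the docs data frame
toy_corpus <- function(n = 8L, seed = 7L, vocab = letters[1:12]) {
  set.seed(seed)
  data.frame(
    docno = sprintf("doc%02d", seq_len(n)),
    text = vapply(seq_len(n), function(i) {
      paste(sample(vocab, 5 + sample.int(10, 1), replace = TRUE),
            collapse = " ")
    }, ""),
    stringsAsFactors = FALSE
  )
}

# single-topic ranked list from an ordered docno vector
as_ranking <- function(docnos, topic = "1", scores = NULL) {
  if (is.null(scores)) scores <- rev(seq_along(docnos))
  out <- data.frame(topic = topic, docno = docnos,
                    rank = seq_along(docnos), score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# single-topic fully judged qrels from named grades
as_qrels <- function(grades, topic = "1") {
  sampled_qrels(data.frame(topic = topic, docno = names(grades),
                           grade = as.integer(grades),
                           stringsAsFactors = FALSE))
}
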