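Package: dsetir
Title: Dataset-Metadata Search with Divergence-from-Randomness Ranking and
    Weighted Query Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained information-retrieval toolkit for collections of
    biomedical dataset-metadata records. Reads the TREC-style XML dialect used
    by dataset-discovery benchmarks (one DOC per dataset with repository-specific
    JSON metadata), normalizes each record into title/keywords/description text,
    filters uninformative records with an English-dictionary plus MeSH word-list
    heuristic, builds an inverted index, and ranks documents with
    divergence-from-randomness weighting models (LGD, InL2, PL2, DPH) alongside
    BM25 and TF-IDF. Queries can be expanded with cosine-similar neighbours from
    word2vec-format embedding spaces under per-source term weights, and with
    Rocchio or Bo1 pseudo-relevance feedback. Retrieval quality is measured with
    P@k (with and without partial relevance), NDCG@k, and the inferred measures
    infAP and infNDCG over sampled graded judgments. Seeded synthetic fixture
    generators produce collections, embedding spaces and qrels with known ground
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
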