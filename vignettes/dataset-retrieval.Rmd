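---
title: "Retrieving biomedical dataset metadata: models, filters and inferred measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving biomedical dataset metadata: models, filters and inferred measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsetir)
```

## The problem

Biomedical dataset-discovery benchmarks index hundreds of thousands of
metadata records harvested from heterogeneous repositories (gene-expression
archives, clinical-trial registries, protein structure databases, imaging
collections, ...). Each record arrives as an XML `DOC` with an identifier,
a title, a repository token and a repository-specific JSON payload; the
retrieval task is to rank these records against short natural-language
needs such as "find data related to diabetes in mice".

Three properties make this harder than ordinary document retrieval:

1. **Schema heterogeneity.** Every repository organizes its JSON
   differently, so the informative text must first be mapped into common
   categories (title, keywords, description).
2. **Uninformative records.** Many records carry only a cryptic laboratory
   identifier (`chr19`, `A375_vitro_vehicle_rep3`) and would pollute the
   index.
3. **Sampled judgments.** Benchmark relevance judgments are graded
   (0/1/2), incomplete (a pooled-but-unjudged class, grade −1) and
   sampled, so evaluation needs *inferred* measures rather than the exact
   ones.

`dsetir` implements the whole chain — normalization, informativeness
filtering, indexing, divergence-from-randomness ranking, weighted
embedding expansion, pseudo-relevance feedback and inferred evaluation —
together with seeded synthetic fixtures so that every stage is testable
offline.

## Category normalization

`parse_collection()` reads the XML dialect; `normalize_record()` reduces
each document to three category texts via per-repository mappings
(`default_category_mappings()`). Mapping entries name flattened JSON keys
(dot-joined paths, arrays indexed positionally) and are matched
case-insensitively as suffixes after dropping dots and underscores,
because mapping vocabularies are usually quoted in a staging-column
convention rather than as literal JSON paths. Values are concatenated in
mapping order with single spaces, which keeps token positions
reproducible. Unknown repositories fall back to
`{title: "title", description: "description"}`. Mappings ship as code but
can be supplied as an editable YAML file (`read_category_mappings()`).

## The informativeness filter

For each category text the filter computes

* `X` — the number of whitespace-delimited words after stripping `,`, `(`
  and `)` (hyphens and underscores stay inside tokens, so `MIP-2` is one
  word);
* `Y1` — words found in an English dictionary word list
  (case-insensitive);
* `Y2` — words *not* in the dictionary but present in a MeSH-derived word
  list (gene symbols like `MIP-2`, `CD69`, `LDLR` live here); a word is
  counted once, English first;
* `score = (Y1 + Y2) / X`, with the sentinel `−1` when `X = 0`.

A title or description is kept when `score > 0` **and** `X > 2`; a
keywords field needs only `score > 0`, because short gene-symbol lists
are informative despite their length. A record is dropped only when all
three categories fail. Both thresholds are strict: a category scoring
exactly 0 (no recognized word) is never kept.

The MeSH word list is harvested flat — descriptor, qualifier,
pharmacological-action and supplementary-record names plus all concept
term synonyms, split on whitespace after removing `,()`, deduplicated —
with no use of the tree-number hierarchy. The packaged English list
(`default_english_words()`) is a curated common-English plus laboratory
vocabulary; any one-word-per-line spell-check list can be substituted,
and the choice only shifts the Y1/Y2 split, not the Y1+Y2 sum, unless a
word is missing from both lists.

```{r filter-example}
lex <- term_lexicon(mesh_words = c("mip-2", "cd69"))
score_field("MIP-2 CD69", lex, "keywords")$score   # 1: kept
score_field("chr19", lex, "title")$score           # 0: dropped
```

## Indexing and ranking

Kept categories are flattened into one bag of words per document
(field-weighted retrieval is out of scope), tokenized by lowercasing and
splitting on every non-alphanumeric character, with tokens longer than 20
characters dropped (configurable). Stopwords are *not* removed from
documents — only from queries — and stemming is off by default since
token-form matching is what the downstream expansion weights assume.

Document scores are sums of per-term contributions. With `tf` the
within-document frequency, `dl` the document length, `avg_dl` its
collection mean, `N` the document count, `df` and `F` the term's document
and collection frequencies, and `qtw` the query-term weight, the core
models are (all logarithms base 2):

* Normalization 2: `tfn = tf · log2(1 + c·avg_dl/dl)`, `c = 1` by
  default;
* **LGD** (log-logistic): `qtw · log2((λ + tfn)/λ)`, `λ = df/N`
  (the document-frequency variant; `F/N` is a one-line config change);
* **InL2**: `qtw · tfn/(tfn+1) · log2((N+1)/(df+0.5))`;
* **PL2**: `qtw · 1/(tfn+1) · (tfn·log2(tfn/λF) + (λF−tfn)·log2 e +
  0.5·log2(2π·tfn))`, `λF = F/N`;
* **DPH**: `qtw · (1−tf/dl)²/(tf+1) · (tf·log2((tf·avg_dl/dl)·(N/F)) +
  0.5·log2(2π·tf·(1−tf/dl)))`;
* **BM25** and **TFIDF** with `k1 = 1.2`, `b = 0.75`.

Scores are linear in `qtw`, so query weights act as multiplicative key
frequencies — the property the 100/20/1 expansion scheme relies on — and
uniform weight scaling never changes an ordering. Ties break by ascending
document identifier, making every ranking byte-reproducible.

An extended set (BB2, IFB2, In_expB2, In_expC2, DLH, DLH13, DFRee,
DFR_BM25) follows the public DFR framework descriptions; additive
constants there vary between engines (which cannot affect ordering), so
these models are exercised for finiteness and determinism but carry no
exact-value guarantees.

Numerical edge cases are explicit: `PL2` requires `F < N` (a term rarer
than one occurrence per document); for terms violating it the bounded
`tfn/(tfn+1)` branch is used with a warning. `DPH`'s
`log2(1 − tf/dl)` factor degenerates when a document consists of one
repeated term; that contribution is defined as 0.

## Query cleaning and weighted expansion

Topics are cleaned by removing boilerplate phrases first (as whole
phrases, longest first — "related to" must go as a unit), then tokenizing
and dropping stopwords. The cleaned terms carry weight 100.

Each embedding space (word2vec text format; `read_word2vec()`) proposes,
per original term, the neighbours whose cosine similarity reaches the
space's threshold: 0.9 for a space trained on a large external abstracts
corpus ("pubmed"), 0.8 for one trained on the collection itself — the
smaller corpus needs a looser threshold to propose anything, and its
proposals are trusted least. Neighbour weights are 20 (pubmed) and 1
(collection). Three further choices matter:

* a per-term, per-space cap of 10 neighbours bounds query drift and cost
  (thresholds alone leave the neighbourhood size unbounded);
* a term proposed twice — by both spaces, or already an original — keeps
  the **maximum** weight, never the sum, so agreement between weak
  sources cannot rival an original term;
* thresholds above 1 are legal and disable a space outright, which gives
  regression tests an exact no-op switch.

Multi-word candidates are split by the index tokenizer, each token
inheriting the candidate's weight. Expanded queries bypass any further
tokenization so the weights survive to scoring.

## Pseudo-relevance feedback

After a first retrieval pass, candidates from the `top_docs = 2` best
documents are scored with the Bose–Einstein Bo1 statistic
`w(t) = tf_x · log2((1+Pn)/Pn) + log2(1+Pn)` with `Pn = F(t)/N` and
`tf_x` the term's frequency in the pseudo-relevant set; the
`terms_per_doc = 2` best per document are taken (read per-document, as
printed in the source configuration; a flag switches to a joint top-4).
Two blending modes:

* **rocchio**: `qtw(t) = α · qtw₀(t)/max qtw₀ + β · w(t)/max w` with
  `α = 1` fixed (only β was ever exposed) and `β = 0.5` by default.
  With `β = 0` this is a pure max-normalization of the original weights:
  order-equivalent, and — because baseline queries carry weight 1 while
  expanded originals carry 100/100 = 1 — *score*-identical to the
  baseline, which is what the no-op regression and determinism checks
  pin down.
* **bo1**: parameter-free; expansion terms join with weight
  `w(t)/max w`, originals untouched.

Original terms are never removed by any expansion stage.

## Evaluation over sampled judgments

Judgments are graded `{−1, 0, 1, 2}` with −1 meaning pooled but not
judged, and carry a per-stratum sampling rate `p` (single stratum,
`p = 1` by default; a fifth qrels column names strata). Measures:

* `P@10` counting grade 1 as relevant (+partial) or not (−partial);
  unjudged and −1 count as non-relevant and the denominator is always
  `k`;
* `NDCG@10` with linear gain (gain = grade) and `log2(rank+1)` discount;
  exponential gain (`2^g − 1`) sits behind a flag since conventions
  differ between evaluation scripts;
* `infAP`: for a sampled-relevant document at rank `k`,
  `êP@k = 1/k + ((k−1)/k) · (|pooled above|/(k−1)) ·
  (r+ε)/(r+n+2ε)` with `r`, `n` the inverse-probability-weighted sampled
  relevant/non-relevant counts above `k` and `ε = 1e−5` (Lidstone
  smoothing, exposed in config); `êP@1 = 1`. The estimate averages over
  *all* sampled-relevant documents, with zero credit for those never
  retrieved — the convention that makes the estimator collapse exactly
  to average precision at `p = 1`;
* `infNDCG`: inverse-probability-weighted DCG over an ideal list built
  from the estimated relevant-grade multiset (sampled counts divided by
  `p`, rounded, never below the observed count), capped at 1.

Topics without a single judged-relevant document have no defined value
and are excluded from means (and listed), rather than scored zero.

## What the synthetic fixtures do and do not show

The fixture generator (`fixture_spec()`, `make_collection()`,
`make_embeddings()`, `make_qrels()`) emulates the *structural* phenomena
the pipeline must survive: repository-specific JSON schemas, missing
tags, a declared fraction of degenerate records copied from real
degenerate content templates, keyword lists mixing dictionary words with
gene-symbol tokens, graded relevance planted as theme words in
descriptions, lexical distractors (non-relevant documents mentioning a
theme word — pooled first, as depth pooling would), orthogonal-cluster
embedding spaces whose neighbourhoods are exactly known, and seeded
judgment subsampling. Everything is deterministic under the seed.

What it does **not** emulate is the statistics of biomedical language:
vocabulary is drawn from a small word list, term frequencies are not
Zipfian, and relevance is driven by planted term overlap. Passing tests
therefore demonstrate contract correctness — formulas, invariants,
determinism, estimator behaviour — not retrieval quality on real
benchmark data. On the real 794,992-record benchmark with its official
qrels and externally trained embedding spaces (inputs this package reads
but does not ship), the flagship configuration — LGD, weighted word2vec
expansion, Rocchio feedback — is the one reported to reach an infNDCG
near 0.45 and infAP near 0.40; reproducing that requires those external
downloads and hours of compute, and is documented here rather than
gated in the test suite.

Problem sizes used by the shipped checks, chosen to keep every property
sharply testable: ranking-oracle corpora of ≤ 10 documents (exact sums to
1e−9), a 1,000-document collection for the expansion no-op regression,
50 random fixtures for the `p = 1` equivalence (1e−10), and a single
300-document pool with 60 relevant documents, 200 subsamples at
`p ∈ {0.3, 0.5}`, for estimator unbiasedness within two Monte-Carlo
standard errors — pools much smaller than that leave the
ratio-of-small-counts bias of the êP estimator visible, which is a
property of the estimator, not of this implementation.

## A complete run

```{r pipeline, eval = FALSE}
bundle <- make_fixture_bundle(fixture_spec(seed = 1, n_docs = 500),
                              "fixtures")
cfg <- run_config(
  collection = bundle$collection, topics = bundle$topics,
  out_dir = "out", qrels = bundle$qrels_full, mesh_files = bundle$mesh,
  model = "LGD",
  vectors_pubmed = bundle$vectors_pubmed,
  vectors_collection = bundle$vectors_collection,
  expansion = expansion_config(),
  prf = prf_params(method = "rocchio", beta = 0.5))
res <- run_pipeline(cfg)
res$report
```

The pipeline writes the TREC-format run file, the per-topic and mean
evaluation report, the filtered corpus, the effective configuration and
an MD5 provenance table side by side; rerunning the same configuration
reproduces every file byte for byte.

## Known limitations

* The extended weighting models are best-effort transcriptions of the
  DFR framework; orderings are trustworthy, absolute scores are not.
* Stratified qrels support covers per-stratum rates supplied in code or
  as a sidecar; official benchmark sampling layouts vary and may need a
  thin conversion step.
* The embedding expansion queries each space with original terms only
  (not with the other space's expansions) — the conservative reading.
* No positional/phrase retrieval, no learning-to-rank, no external
  re-ranking; these are explicit non-goals.
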