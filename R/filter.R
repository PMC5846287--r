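#' Split category text into filter words
#'
#' The informativeness filter counts whitespace-delimited words after
#' stripping the characters `,`, `(` and `)` — hyphens and underscores stay
#' inside tokens, so `"MIP-2"` is a single word (which is exactly why such
#' gene/protein symbols are not English words but can be MeSH words). This is
#' deliberately different from the index tokenizer ([tokenize()]).
#'
#' @param text Character scalar.
#' @return Character vector of words (original case preserved).
#' @export
filter_words <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  cleaned <- gsub("[,()]", "", text)
  toks <- strsplit(trimws(cleaned), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Score one category's text for informativeness
#'
#' Implements the stepwise scoring heuristic that decides whether a record's
#' category text carries indexable content:
#'
#' * `X` — total number of words in the text;
#' * `Y1` — words recognized as English (dictionary lookup,
#'   case-insensitive);
#' * `Y2` — words *not* recognized as English but found in the MeSH word set
#'   (a word counts once, English first);
#' * if `X = 0` the score is the sentinel `-1`; otherwise
#'   `score = (Y1 + Y2) / X`;
#' * the record is kept when `score > 0` and, for title and description
#'   only, additionally `X > 2`. Keywords need only `score > 0` (gene-symbol
#'   lists like "MIP-2 CD69" are short but informative).
#'
#' @param text Category text (character scalar).
#' @param lexicon A [term_lexicon()].
#' @param category One of `"title"`, `"keywords"`, `"description"`.
#' @return A `field_score`: list with `category`, `X`, `Y1`, `Y2`, `score`,
#'   `keep`.
#' @examples
#' lex <- term_lexicon(english_words = c("acute", "liver"),
#'                     mesh_words = c("mip-2", "cd69"))
#' score_field("MIP-2 CD69", lex, "keywords")$score  # 1.0
#' @export
score_field <- function(text, lexicon,
                        category = c("title", "keywords", "description")) {
  category <- match.arg(category)
  stopifnot(inherits(lexicon, "term_lexicon"))
  words <- tolower(filter_words(text))
  X <- length(words)
  if (X == 0L) {
    return(structure(list(category = category, X = 0L, Y1 = 0L, Y2 = 0L,
                          score = -1, keep = FALSE), class = "field_score"))
  }
  is_eng <- .in_set(words, lexicon$english)
  is_mesh <- .in_set(words, lexicon$mesh)
  Y1 <- sum(is_eng)
  Y2 <- sum(!is_eng & is_mesh)
  score <- (Y1 + Y2) / X
  keep <- if (category == "keywords") score > 0 else (score > 0 && X > 2L)
  structure(list(category = category, X = X, Y1 = as.integer(Y1),
                 Y2 = as.integer(Y2), score = score, keep = keep),
            class = "field_score")
}

#' Decide which categories of a normalized record to index
#'
#' Scores the three category texts with [score_field()] and drops the record
#' when no category is kept.
#'
#' @param record A `normalized_record`.
#' @param lexicon A [term_lexicon()].
#' @return List with `docno`, `scores` (named list of `field_score`s),
#'   logical `keep_title` / `keep_keywords` / `keep_description`, and `drop`
#'   (`TRUE` when all three are `FALSE`).
#' @export
filter_record <- function(record, lexicon) {
  s <- list(
    title = score_field(record$title_text, lexicon, "title"),
    keywords = score_field(record$keywords_text, lexicon, "keywords"),
    description = score_field(record$description_text, lexicon, "description")
  )
  kt <- s$title$keep; kk <- s$keywords$keep; kd <- s$description$keep
  list(docno = record$docno, repository = record$repository, scores = s,
       keep_title = kt, keep_keywords = kk, keep_description = kd,
       drop = !(kt || kk || kd))
}

#' Filter a whole collection of normalized records
#'
#' @param records List of `normalized_record`s.
#' @param lexicon A [term_lexicon()].
#' @param verbose Log per-repository drop counts.
#' @return Data frame with one row per record: `docno`, `repository`,
#'   `keep_title`, `keep_keywords`, `keep_description`, `drop`; attribute
#'   `drop_counts` holds dropped-record counts per repository.
#' @export
filter_collection <- function(records, lexicon, verbose = FALSE) {
  rows <- lapply(records, function(r) {
    f <- filter_record(r, lexicon)
    data.frame(docno = f$docno, repository = f$repository,
               keep_title = f$keep_title, keep_keywords = f$keep_keywords,
               keep_description = f$keep_description, drop = f$drop,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dc <- if (any(out$drop)) table(out$repository[out$drop]) else table(character(0))
  if (verbose) {
    .msg("informativeness filter: dropped ", sum(out$drop), " of ",
         nrow(out), " records")
    for (r in names(dc)) .msg("  ", r, ": ", dc[[r]], " dropped")
  }
  attr(out, "drop_counts") <- dc
  out
}
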