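#' Tokenize text for indexing and retrieval
#'
#' Lowercases the input and splits it on every non-alphanumeric character, so
#' that e.g. `"MIP-2"` becomes `c("mip", "2")`. Tokens longer than `max_len`
#' characters are dropped (very long tokens in dataset metadata are almost
#' always accession strings or concatenated identifiers that no query will
#' match). Empty strings never appear in the output.
#'
#' This is the single tokenizer used for documents at indexing time and for
#' query terms, so that query and index vocabularies agree.
#'
#' @param text Character vector; elements are concatenated with spaces before
#'   tokenization.
#' @param max_len Maximum token length retained (default 20).
#' @return Character vector of lowercase alphanumeric tokens (possibly empty).
#' @examples
#' tokenize("Diabetes, type-2")  # "diabetes" "type" "2"
#' @export
tokenize <- function(text, max_len = 20L) {
  if (length(text) == 0L) return(character(0))
  text <- paste(text, collapse = " ")
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks[nchar(toks) <= max_len]
}
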