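#' Harvest a flat word list from MeSH XML vocabulary files
#'
#' Collects term strings from the 2017-schema MeSH XML files and reduces them
#' to a deduplicated set of lowercase words. The trees harvested depend on the
#' file's root element:
#'
#' * `DescriptorRecordSet` (desc): `DescriptorName` and `ConceptList`
#' * `PharmacologicalActionSet` (pa): `DescriptorName` and
#'   `PharmacologicalActionSubstanceList`
#' * `QualifierRecordSet` (qual): `QualifierName` and `ConceptList`
#' * `SupplementalRecordSet` (suppl): `SupplementalRecordName` and
#'   `ConceptList`
#'
#' All `<String>` term texts under those trees (descriptor names and every
#' concept/term synonym) are taken; the characters `,`, `(` and `)` are
#' removed and each name is split on whitespace, so `"Abdomen, Acute"`
#' contributes the words `abdomen` and `acute`. Files whose root element is
#' not one of the four known schemas are skipped with a warning.
#'
#' @param mesh_files Character vector of MeSH XML file paths.
#' @return Character vector: sorted unique lowercase words. Empty (with a
#'   warning) for an empty file set.
#' @export
build_mesh_lexicon <- function(mesh_files) {
  if (length(mesh_files) == 0L) {
    warning("no MeSH files supplied; MeSH word set is empty", call. = FALSE)
    return(character(0))
  }
  trees <- list(
    DescriptorRecordSet = c("DescriptorName", "ConceptList"),
    PharmacologicalActionSet = c("DescriptorName",
                                 "PharmacologicalActionSubstanceList"),
    QualifierRecordSet = c("QualifierName", "ConceptList"),
    SupplementalRecordSet = c("SupplementalRecordName", "ConceptList")
  )
  words <- character(0)
  for (f in mesh_files) {
    doc <- xml2::read_xml(f, encoding = "UTF-8")
    root <- xml2::xml_name(xml2::xml_root(doc))
    if (!root %in% names(trees)) {
      warning("unknown MeSH schema root '", root, "' in ", f,
              "; file skipped", call. = FALSE)
      next
    }
    # harvest every String leaf under the named trees (descriptor/qualifier/
    # supplemental names and all concept-term synonyms)
    xp <- paste(sprintf("//%s//String", trees[[root]]), collapse = " | ")
    strs <- xml2::xml_text(xml2::xml_find_all(doc, xp))
    words <- c(words, mesh_words_from_names(strs))
  }
  sort(unique(words))
}

#' Turn MeSH name strings into filter words
#'
#' Applies the harvest rules: remove `,`, `(`, `)`; split on whitespace;
#' lowercase; deduplicate.
#'
#' @param names Character vector of term name strings.
#' @return Character vector of unique lowercase words.
#' @export
mesh_words_from_names <- function(names) {
  cleaned <- gsub("[,()]", "", names)
  toks <- as.character(unlist(strsplit(tolower(cleaned), "\\s+"),
                              use.names = FALSE))
  unique(toks[nzchar(toks)])
}

#' The packaged English word list
#'
#' A curated list of common English plus laboratory vocabulary shipped with
#' the package, one lowercase word per line. Serves as the dictionary for the
#' informativeness filter's "recognized as English" test; any spell-check
#' word list in the same one-word-per-line format may be substituted.
#'
#' @param path Optional path to an alternative word list file.
#' @return Character vector of lowercase words.
#' @export
default_english_words <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "english-words.txt", package = "dsetir",
                        mustWork = TRUE)
  }
  read_wordlist(path)
}

#' Read / write a one-word-per-line lexicon cache
#'
#' @param path Text file path, one word per line; blank lines and `#`
#'   comments ignored on read.
#' @return For `read_wordlist`, a character vector of unique lowercase words.
#' @export
read_wordlist <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(tolower(x))
}

#' @rdname read_wordlist
#' @param words Character vector of words.
#' @export
write_wordlist <- function(words, path) {
  writeLines(sort(unique(tolower(words))), path, useBytes = TRUE)
  invisible(path)
}

#' Build a term lexicon for the informativeness filter
#'
#' Bundles the English dictionary word set and the MeSH-derived word set,
#' both lowercased and deduplicated, with a provenance manifest. Membership
#' tests ([score_field()]) are case-insensitive.
#'
#' @param english_words Character vector (default: the packaged list).
#' @param mesh_words Character vector, e.g. from [build_mesh_lexicon()] or a
#'   cached word list.
#' @param manifest Named character vector of provenance notes per source.
#' @return A `term_lexicon` object.
#' @export
term_lexicon <- function(english_words = default_english_words(),
                         mesh_words = character(0),
                         manifest = character(0)) {
  eng <- unique(tolower(english_words))
  msh <- unique(tolower(mesh_words))
  structure(
    list(
      english = new.env(parent = emptyenv()),
      mesh = new.env(parent = emptyenv()),
      english_words = eng,
      mesh_words = msh,
      source_manifest = manifest
    ),
    class = "term_lexicon"
  ) -> lex
  for (w in eng) assign(w, TRUE, envir = lex$english)
  for (w in msh) assign(w, TRUE, envir = lex$mesh)
  lex
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat("<term_lexicon> ", length(x$english_words), " English words, ",
      length(x$mesh_words), " MeSH words\n", sep = "")
  invisible(x)
}

.in_set <- function(words, env) {
  vapply(words, function(w) !is.null(env[[w]]), logical(1), USE.NAMES = FALSE)
}
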