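#' Write / read TREC run files
#'
#' Runs use the standard six-column `trec_eval` format
#' `topic Q0 docno rank score tag`, one row per retrieved document, scores
#' printed with six decimals.
#'
#' @param ranked A `ranked_list` (from [search()]) or a list of them (one
#'   per topic).
#' @param path Output path.
#' @param tag Run tag; defaults to the ranked list's own tag.
#' @return `path`, invisibly.
#' @export
write_run <- function(ranked, path, tag = NULL) {
  if (inherits(ranked, "ranked_list")) ranked <- list(ranked)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in ranked) {
    rt <- tag %||% attr(r, "run_tag") %||% "run"
    if (nrow(r) == 0L) next
    lines <- sprintf("%s Q0 %s %d %.6f %s", r$topic, r$docno, r$rank,
                     r$score, rt)
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_run
#' @return For `parse_run`, a data frame `topic`, `docno`, `rank`, `score`
#'   with the run tag as attribute `run_tag`.
#' @export
parse_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- data.frame(topic = character(0), docno = character(0),
                      rank = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("ranked_list", "data.frame")
    return(out)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 0L) != 6L)
  if (length(bad)) {
    stop("malformed run line ", bad[1], ": expected 6 fields", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  out <- data.frame(topic = m[, 1], docno = m[, 3],
                    rank = as.integer(m[, 4]), score = as.numeric(m[, 5]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  attr(out, "run_tag") <- m[1, 6]
  out
}

#' Graded, possibly sampled relevance judgments
#'
#' Wraps a judgment table with per-stratum sampling rates. Grades are
#' `-1` (pooled but not judged), `0` (not relevant), `1` (partially
#' relevant), `2` (relevant). The default is a single stratum sampled
#' exhaustively (`p = 1`); stratified sampled qrels carry a stratum label
#' per row and a named rate vector.
#'
#' @param judgments Data frame with columns `topic`, `docno`, `grade` and
#'   optionally `stratum` (default `"s1"`).
#' @param p Named numeric vector of sampling rates per stratum in (0, 1].
#' @return A `sampled_qrels` data frame with attribute `p`.
#' @export
sampled_qrels <- function(judgments, p = NULL) {
  stopifnot(all(c("topic", "docno", "grade") %in% names(judgments)))
  if (!"stratum" %in% names(judgments)) judgments$stratum <- "s1"
  judgments$topic <- as.character(judgments$topic)
  judgments$docno <- as.character(judgments$docno)
  judgments$grade <- as.integer(judgments$grade)
  if (!all(judgments$grade %in% c(-1L, 0L, 1L, 2L))) {
    stop("grades must be in {-1, 0, 1, 2}", call. = FALSE)
  }
  key <- paste(judgments$topic, judgments$docno)
  if (anyDuplicated(key)) {
    stop("duplicate (topic, docno) pair in qrels: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  strata <- unique(judgments$stratum)
  if (is.null(p)) p <- stats::setNames(rep(1, length(strata)), strata)
  if (!all(strata %in% names(p))) {
    stop("missing sampling rate for stratum: ",
         paste(setdiff(strata, names(p)), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(p > 0), all(p <= 1))
  out <- judgments[, c("topic", "docno", "grade", "stratum")]
  rownames(out) <- NULL
  class(out) <- c("sampled_qrels", "data.frame")
  attr(out, "p") <- p
  out
}

#' Parse / write TREC qrels
#'
#' Four whitespace-separated columns `topic iteration docno grade`, with an
#' optional fifth `stratum` column for stratified sampled judgments.
#' Unknown grades and duplicate (topic, docno) pairs are rejected with the
#' offending line.
#'
#' @param path Qrels file path.
#' @param p Optional named per-stratum sampling rates (see
#'   [sampled_qrels()]).
#' @return A `sampled_qrels` object.
#' @export
parse_qrels <- function(path, p = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    return(sampled_qrels(data.frame(topic = character(0),
                                    docno = character(0),
                                    grade = integer(0))))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- vapply(parts, length, 0L)
  bad <- which(!nf %in% c(4L, 5L))
  if (length(bad)) {
    stop("malformed qrels line ", bad[1], ": expected 4 or 5 fields",
         call. = FALSE)
  }
  grades <- suppressWarnings(as.integer(vapply(parts, `[`, "", 4L)))
  badg <- which(is.na(grades) | !grades %in% c(-1L, 0L, 1L, 2L))
  if (length(badg)) {
    stop("qrels line ", badg[1], ": grade must be one of -1, 0, 1, 2",
         call. = FALSE)
  }
  df <- data.frame(
    topic = vapply(parts, `[`, "", 1L),
    docno = vapply(parts, `[`, "", 3L),
    grade = grades,
    stringsAsFactors = FALSE
  )
  if (any(nf == 5L)) {
    df$stratum <- ifelse(nf == 5L, vapply(parts, function(x) x[5], ""), "s1")
  }
  sampled_qrels(df, p = p)
}

#' @rdname parse_qrels
#' @param qrels A `sampled_qrels` object.
#' @param write_stratum Emit the fifth stratum column.
#' @export
write_qrels <- function(qrels, path, write_stratum = FALSE) {
  lines <- if (write_stratum) {
    sprintf("%s 0 %s %d %s", qrels$topic, qrels$docno, qrels$grade,
            qrels$stratum)
  } else {
    sprintf("%s 0 %s %d", qrels$topic, qrels$docno, qrels$grade)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
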