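# Abstract corpora: parsing, sentence splitting, training-subset selection.

#' Construct an abstract record
#'
#' @param pmid Identifier string.
#' @param title Title sentence (may be empty only when the body is not).
#' @param body Character vector of body sentences.
#' @return Object of class `abstract`.
#' @export
abstract <- function(pmid, title = "", body = character()) {
  stopifnot(is.character(pmid), length(pmid) == 1L, nzchar(pmid))
  title <- as.character(title)
  body <- as.character(body)
  if (!nzchar(title) && length(body) == 0L) {
    stop("abstract ", pmid, " has neither title nor body")
  }
  structure(list(pmid = pmid, title = title, body = body),
            class = "abstract")
}

#' @export
print.abstract <- function(x, ...) {
  cat("<abstract ", x$pmid, "> ", x$title, "\n  ",
      length(x$body), " body sentence(s)\n", sep = "")
  invisible(x)
}

.SPLIT_ABBREV <- c("i.e", "e.g", "etc", "vs", "cf", "fig", "figs", "ref",
                   "al", "dr", "st", "no", "approx")

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at `.`, `!` or `?`
#' followed by whitespace and an upper-case letter or digit, provided the
#' terminator is outside parentheses and the preceding word is not a known
#' abbreviation (`i.e.`, `e.g.`, `etc.`, `Fig.`, ...).
#'
#' @param text Character scalar.
#' @return Character vector of sentences (empty for blank input).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(character(0))
  }
  chs <- strsplit(text, "")[[1]]
  n <- length(chs)
  depth <- 0L
  bounds <- integer(0)
  for (i in seq_len(n)) {
    c <- chs[i]
    if (c == "(") depth <- depth + 1L
    if (c == ")") depth <- max(0L, depth - 1L)
    if (!(c %in% c(".", "!", "?")) || depth > 0L) next
    j <- i + 1L
    while (j <= n && chs[j] %in% c(" ", "\t")) j <- j + 1L
    if (j > n) {
      bounds <- c(bounds, i)
      next
    }
    if (j == i + 1L) next              # no whitespace after the terminator
    if (!grepl("[A-Z0-9]", chs[j])) next
    # word immediately before the terminator
    k <- i - 1L
    while (k >= 1L && !(chs[k] %in% c(" ", "\t"))) k <- k - 1L
    word <- paste(chs[seq.int(k + 1L, i - 1L)], collapse = "")
    word <- gsub("\\.$", "", word)
    if (tolower(word) %in% .SPLIT_ABBREV) next
    bounds <- c(bounds, i)
  }
  if (length(bounds) == 0L || bounds[length(bounds)] < n) {
    bounds <- c(bounds, n)
  }
  starts <- c(1L, bounds[-length(bounds)] + 1L)
  out <- vapply(seq_along(bounds), function(k) {
    trimws(paste(chs[starts[k]:bounds[k]], collapse = ""))
  }, "")
  out[nzchar(out)]
}

.parse_corpus_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    pmid <- if (length(parts) >= 1L) trimws(parts[1L]) else ""
    title <- if (length(parts) >= 2L) trimws(parts[2L]) else ""
    ab <- if (length(parts) >= 3L) trimws(parts[3L]) else ""
    if (!nzchar(pmid) || (!nzchar(title) && !nzchar(ab))) {
      warning("skipping malformed corpus record: ",
              substr(ln, 1L, 60L))
      next
    }
    out[[length(out) + 1L]] <- abstract(pmid, title, split_sentences(ab))
  }
  out
}

.parse_corpus_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  rec <- list()
  tag <- ""
  flush <- function(rec) {
    pmid <- trimws(rec$PMID %||% "")
    title <- trimws(rec$TI %||% "")
    ab <- trimws(rec$AB %||% "")
    if (!nzchar(pmid) || (!nzchar(title) && !nzchar(ab))) {
      if (length(rec)) {
        warning("skipping MEDLINE record without usable fields (PMID '",
                pmid, "')")
      }
      return(NULL)
    }
    abstract(pmid, title, split_sentences(ab))
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      a <- flush(rec)
      if (!is.null(a)) out[[length(out) + 1L]] <- a
      rec <- list()
      tag <- ""
      next
    }
    if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
      tag <- trimws(sub("-.*$", "", ln))
      val <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
      if (tag == "PMID" && !is.null(rec$PMID)) {
        # new record without a separating blank line
        a <- flush(rec)
        if (!is.null(a)) out[[length(out) + 1L]] <- a
        rec <- list()
      }
      rec[[tag]] <- paste(c(rec[[tag]], val), collapse = " ")
    } else if (grepl("^\\s+", ln) && nzchar(tag)) {
      rec[[tag]] <- paste(rec[[tag]], trimws(ln))
    }
  }
  a <- flush(rec)
  if (!is.null(a)) out[[length(out) + 1L]] <- a
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an abstract corpus
#'
#' Supports a 3-column TSV dialect (`pmid<TAB>title<TAB>abstract`) and the
#' MEDLINE flat format (`PMID- `, `TI  - `, `AB  - ` fields with indented
#' continuation lines, records separated by blank lines). Abstract text is
#' segmented with [split_sentences()]. Records with neither title nor body
#' are skipped with a warning.
#'
#' @param path File path.
#' @param format `"tsv"` or `"medline"`.
#' @return List of [abstract()] objects in file order.
#' @export
parse_corpus <- function(path, format = c("tsv", "medline")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         tsv = .parse_corpus_tsv(path),
         medline = .parse_corpus_medline(path))
}

#' Write a corpus in the TSV dialect
#'
#' Body sentences are joined with single spaces; `parse_corpus()` on the
#' result recovers the same `(pmid, title, body)` triples for well-formed
#' sentences.
#'
#' @param corpus List of `abstract` objects.
#' @param path Output file path.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(a) {
    paste(a$pmid, a$title, paste(a$body, collapse = " "), sep = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Select pattern-induction training abstracts by title matching
#'
#' An abstract is kept when its tagged title matches at least one seed
#' pattern (full pattern matching with entity placeholders instantiated by
#' dictionary tagging, not substring search): a title that matches a
#' regulation pattern is likely to head an abstract describing regulation
#' relationships.
#'
#' @param corpus List of `abstract` objects.
#' @param seeds A [pattern_set()] of seed patterns.
#' @param lexicon A `gene_lexicon`.
#' @param query_tf Optional query TF; with `NULL` all tagged entities count
#'   as placeholder fillers.
#' @param quiet Suppress the selection-count message.
#' @return The selected abstracts, in corpus order.
#' @export
select_training_abstracts <- function(corpus, seeds, lexicon,
                                      query_tf = NULL, quiet = FALSE) {
  stopifnot(inherits(seeds, "pattern_set"))
  if (nrow(seeds) == 0L) stop("seed pattern set is empty")
  keep <- vapply(corpus, function(a) {
    if (!nzchar(a$title)) return(FALSE)
    tg <- tag_sentence(a$title, query_tf, lexicon,
                       sentence_index = -1L,
                       abstract_length = length(a$body))
    for (p in seeds$pattern) {
      if (nrow(match_pattern(tg, p)) > 0L) return(TRUE)
    }
    FALSE
  }, logical(1L))
  if (!quiet) {
    message(sprintf("selected %d of %d abstracts by seed-title match",
                    sum(keep), length(corpus)))
  }
  corpus[keep]
}
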