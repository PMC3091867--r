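# Dictionary-based entity and action-word tagging.
#
# A lexicon holds transcription-factor (TF) and gene dictionaries (canonical
# symbol plus synonym/alias variants), a key-verb list (lemma plus inflected
# and nominal surface forms, e.g. activate/activates/activation) and an
# exception-word list of dictionary names that collide with common English
# words and must never be tagged.

#' Normalize a gene approved name containing parentheses
#'
#' Nomenclature approved names often embed an alternate symbol in
#' parentheses, e.g. `"ATP-binding cassette sub-family A (ABC1), member 4"`.
#' Each parenthesized group is removed from the name and additionally kept as
#' a variant of its own, so both the cleaned long name and the short form are
#' matchable. Names without parentheses pass through unchanged.
#'
#' @param raw_name Non-empty character scalar.
#' @return Character vector: the name with all parenthesized groups removed
#'   (whitespace collapsed), followed by the content of each group. An
#'   unbalanced parenthesis is kept as a literal character with a warning.
#' @examples
#' normalize_gene_name("ATP-binding cassette sub-family A (ABC1), member 4")
#' normalize_gene_name("EPO")
#' @export
normalize_gene_name <- function(raw_name) {
  stopifnot(is.character(raw_name), length(raw_name) == 1L, nzchar(raw_name))
  n_open <- lengths(regmatches(raw_name, gregexpr("(", raw_name, fixed = TRUE)))
  n_close <- lengths(regmatches(raw_name, gregexpr(")", raw_name, fixed = TRUE)))
  if (n_open != n_close) {
    warning("unbalanced parentheses in gene name: ", raw_name,
            " (orphan bracket kept literally)")
  }
  if (!grepl("\\([^()]*\\)", raw_name)) {
    return(raw_name)
  }
  groups <- character(0)
  remainder <- raw_name
  # innermost-first so nested groups unwrap deterministically
  while (grepl("\\([^()]*\\)", remainder)) {
    m <- regmatches(remainder, gregexpr("\\([^()]*\\)", remainder))[[1]]
    groups <- c(groups, trimws(substr(m, 2L, nchar(m) - 1L)))
    remainder <- gsub("\\s*\\([^()]*\\)", "", remainder)
  }
  remainder <- trimws(gsub("\\s+", " ", remainder))
  out <- c(remainder, groups)
  out[nzchar(out)]
}

#' Tokenize a sentence
#'
#' Splits on whitespace and punctuation while keeping hyphenated names
#' (`"HIF-1"`, `"element-binding"`) as single tokens, because dictionary
#' entries contain internal hyphens. Parentheses, brackets, commas and other
#' clause punctuation become standalone tokens (parentheses are needed for
#' abbreviation detection); trailing periods are stripped from tokens.
#'
#' @param x Character scalar.
#' @return Character vector of tokens (zero-length for blank input).
#' @export
tokenize_sentence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x) || !nzchar(trimws(x))) {
    return(character(0))
  }
  x <- gsub("([][(){},;:!?\"])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks <- sub("\\.+$", "", toks)
  toks[nzchar(toks)]
}

#' Detect abbreviation long forms to mask from key-verb matching
#'
#' Biomedical names are commonly introduced as `long form (SHORT)`. Words
#' inside the spelled-out long form must not be mistaken for action words:
#' in `"cAMP response element-binding protein (CREB)"` the word "response"
#' is part of the name, not a regulation verb. Short forms are aligned to
#' the preceding words by Schwartz--Hearst-style initial-character matching,
#' scanning right to left from the open parenthesis.
#'
#' @param tokens Character vector of tokens (see [tokenize_sentence()]).
#' @return List of integer vectors `c(start, end)` (1-based, inclusive token
#'   ranges) covering detected long forms; empty list when none.
#' @export
mask_abbreviation_longforms <- function(tokens) {
  spans <- list()
  n <- length(tokens)
  if (n < 4L) {
    return(spans)
  }
  for (i in which(tokens == "(")) {
    if (i < 2L || i + 2L > n || tokens[i + 2L] != ")") next
    short <- tokens[i + 1L]
    sf <- strsplit(tolower(gsub("[^A-Za-z0-9]", "", short)), "")[[1]]
    if (length(sf) < 2L) next
    max_words <- min(length(sf) + 5L, length(sf) * 2L)
    lo <- max(1L, i - max_words)
    start_tok <- .find_long_form(sf, tokens[lo:(i - 1L)])
    if (!is.na(start_tok)) {
      spans[[length(spans) + 1L]] <- c(lo + start_tok - 1L, i - 1L)
    }
  }
  spans
}

# Right-to-left character alignment of the short form against candidate
# long-form tokens; the first short-form character must sit at a word start.
# Returns the index (within lf_tokens) of the first long-form token, or NA.
.find_long_form <- function(sf, lf_tokens) {
  chars <- character(0)
  tok_of <- integer(0)
  word_start <- logical(0)
  for (k in seq_along(lf_tokens)) {
    tc <- strsplit(tolower(lf_tokens[k]), "")[[1]]
    if (length(tc) == 0L) next
    ws <- c(TRUE, !grepl("[a-z0-9]", tc[-length(tc)]))
    chars <- c(chars, tc)
    tok_of <- c(tok_of, rep(k, length(tc)))
    word_start <- c(word_start, ws)
  }
  s <- length(sf)
  l <- length(chars)
  if (l == 0L) {
    return(NA_integer_)
  }
  while (s > 0L) {
    while (l > 0L &&
           (chars[l] != sf[s] || (s == 1L && !word_start[l]))) {
      l <- l - 1L
    }
    if (l == 0L) {
      return(NA_integer_)
    }
    s <- s - 1L
    l <- l - 1L
  }
  tok_of[l + 1L]
}

#' Construct a lexicon
#'
#' @param tf Named list (or named character vector) mapping TF canonical
#'   symbols to character vectors of variants.
#' @param gene Same structure for the gene dictionary.
#' @param verbs Named list mapping key-verb lemmas to surface forms
#'   (inflections and noun forms); everything is lower-cased.
#' @param exceptions Character vector of words never to tag (compared
#'   case-insensitively), e.g. `"To"`, `"Alpha"`, `"Cell"`.
#' @return Object of class `gene_lexicon`.
#' @export
lexicon <- function(tf = list(), gene = list(), verbs = list(),
                    exceptions = character()) {
  tidy_dict <- function(d, label) {
    d <- lapply(d, function(v) unique(trimws(as.character(v))))
    if (length(d) && (is.null(names(d)) || any(!nzchar(names(d))))) {
      stop("every ", label, " entry needs a non-empty canonical symbol")
    }
    ex <- tolower(exceptions)
    out <- list()
    for (canonical in names(d)) {
      variants <- unique(c(canonical, d[[canonical]]))
      variants <- variants[nzchar(variants)]
      variants <- variants[!(tolower(variants) %in% ex)]
      if (length(variants) == 0L) {
        warning(label, " entry '", canonical,
                "' dropped: all variants are exception words")
        next
      }
      if (!is.null(out[[canonical]])) {
        variants <- unique(c(out[[canonical]], variants))
      }
      out[[canonical]] <- variants
    }
    out
  }
  verbs <- lapply(verbs, function(v) unique(tolower(trimws(as.character(v)))))
  if (length(verbs)) {
    names(verbs) <- tolower(names(verbs))
    verbs <- mapply(function(lemma, forms) unique(c(lemma, forms[nzchar(forms)])),
                    names(verbs), verbs, SIMPLIFY = FALSE)
  }
  obj <- structure(
    list(tf = tidy_dict(tf, "TF"),
         gene = tidy_dict(gene, "gene"),
         verbs = verbs,
         exceptions = unique(exceptions)),
    class = "gene_lexicon"
  )
  obj$index <- .build_lexicon_index(obj)
  obj$verb_map <- .build_verb_map(obj)
  obj
}

# Variant lookup tables. Short all-caps symbols (<= 4 characters) are matched
# case-sensitively to curb homonym false positives ("TO" vs "To"); everything
# else is case-insensitive on lower-cased token keys.
.build_lexicon_index <- function(lex) {
  rows <- list()
  add <- function(kind, dict) {
    for (canonical in names(dict)) {
      for (variant in dict[[canonical]]) {
        toks <- tokenize_sentence(variant)
        if (length(toks) == 0L) next
        cs <- nchar(variant) <= 4L && variant == toupper(variant) &&
          grepl("[A-Z]", variant)
        key <- paste(if (cs) toks else tolower(toks), collapse = " ")
        rows[[length(rows) + 1L]] <<- data.frame(
          kind = kind, canonical = canonical, variant = variant,
          key = key, ntok = length(toks), cs = cs,
          stringsAsFactors = FALSE)
      }
    }
  }
  add("TF", lex$tf)
  add("GENE", lex$gene)
  if (length(rows) == 0L) {
    return(data.frame(kind = character(), canonical = character(),
                      variant = character(), key = character(),
                      ntok = integer(), cs = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

.build_verb_map <- function(lex) {
  forms <- unlist(lex$verbs, use.names = FALSE)
  lemma <- rep(names(lex$verbs), lengths(lex$verbs))
  # first lemma wins if a surface form is shared
  keep <- !duplicated(forms)
  stats::setNames(lemma[keep], forms[keep])
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat("<gene_lexicon>\n",
      "  TF entries:   ", length(x$tf), "\n",
      "  gene entries: ", length(x$gene), "\n",
      "  key verbs:    ", length(x$verbs), "\n",
      "  exceptions:   ", length(x$exceptions), "\n", sep = "")
  invisible(x)
}

.read_dict_file <- function(path, label) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("empty dictionary file: ", path)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 1L
  canonical <- trimws(vapply(parts, `[`, "", 1L))
  variants <- lapply(parts, function(p) {
    if (length(p) >= 2L) trimws(strsplit(p[[2L]], "|", fixed = TRUE)[[1]])
    else character(0)
  })
  if (any(!nzchar(canonical))) {
    stop("record without canonical symbol in ", label, " file: ", path)
  }
  stats::setNames(variants, canonical)
}

#' Load TF/gene/key-verb/exception dictionaries from files
#'
#' Dictionary files are UTF-8 TSV, one entry per line:
#' `canonical<TAB>variant1|variant2|...`; the key-verb file uses
#' `lemma<TAB>form1|form2|...`; the exception file has one word per line.
#' Gene names are passed through [normalize_gene_name()] so parenthesized
#' alternate symbols become variants of their own, and any variant equal
#' (case-insensitively) to an exception word is dropped. Duplicate canonical
#' symbols have their variant sets merged.
#'
#' @param tf_path,gene_path,verbs_path,exceptions_path File paths.
#' @param quiet Suppress the per-dictionary count message.
#' @return A `gene_lexicon` object.
#' @export
load_lexicons <- function(tf_path, gene_path, verbs_path, exceptions_path,
                          quiet = FALSE) {
  for (p in c(tf_path, gene_path, verbs_path, exceptions_path)) {
    if (!file.exists(p)) stop("no such file: ", p)
  }
  exceptions <- readLines(exceptions_path, encoding = "UTF-8", warn = FALSE)
  exceptions <- trimws(exceptions)
  exceptions <- exceptions[nzchar(exceptions) & !startsWith(exceptions, "#")]

  tf_raw <- .read_dict_file(tf_path, "TF")
  gene_raw <- .read_dict_file(gene_path, "gene")
  gene_raw <- lapply(gene_raw, function(vv) {
    unique(unlist(lapply(vv, normalize_gene_name), use.names = FALSE))
  })
  verbs_raw <- .read_dict_file(verbs_path, "key-verb")

  # merge duplicate canonical symbols
  merge_dups <- function(d) {
    if (!anyDuplicated(names(d))) return(d)
    tapply(d, names(d), function(vs) unique(unlist(vs, use.names = FALSE)),
           simplify = FALSE)
  }
  lex <- lexicon(tf = merge_dups(tf_raw), gene = merge_dups(gene_raw),
                 verbs = merge_dups(verbs_raw), exceptions = exceptions)
  if (!quiet) {
    message(sprintf("loaded %d TF, %d gene, %d key-verb entries (%d exception words)",
                    length(lex$tf), length(lex$gene), length(lex$verbs),
                    length(lex$exceptions)))
  }
  lex
}

.empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), label = character(),
             variant = character(), canonical = character(),
             stringsAsFactors = FALSE)
}

.in_spans <- function(j, spans) {
  for (s in spans) {
    if (j >= s[1L] && j <= s[2L]) return(TRUE)
  }
  FALSE
}

.resolve_query_tf <- function(query_tf, lex) {
  if (is.null(query_tf)) {
    return(NULL)
  }
  q <- tolower(trimws(query_tf))
  for (canonical in names(lex$tf)) {
    if (q %in% tolower(lex$tf[[canonical]])) {
      return(canonical)
    }
  }
  stop("query TF '", query_tf, "' not found in the TF dictionary")
}

#' Tag a sentence with TF, target-gene and key-verb mentions
#'
#' Longest-match dictionary tagging over tokens. Matching is
#' case-insensitive except for short all-caps symbols (4 characters or
#' fewer), which must match exactly. A name present in both dictionaries is
#' resolved through the TF dictionary (the TF has priority over the gene in
#' homonym cases). Mentions of the query TF are labeled `TF` (only the first
#' occurrence is kept); every other dictionary hit is a target gene `TG`, so
#' a sentence carries at most one TF mention. Key-verb surface forms are
#' labeled `KEYVERB` unless they fall inside an abbreviation long form
#' (see [mask_abbreviation_longforms()]) or inside an entity mention.
#'
#' @param sentence Character scalar (or an already tokenized character
#'   vector).
#' @param query_tf Query TF symbol or synonym; `NULL` tags all entities as
#'   `TG` (used when matching seed patterns against titles).
#' @param lexicon A `gene_lexicon`.
#' @param sentence_index Position of the sentence in its abstract: `-1` for
#'   the title, `0`-based within the body.
#' @param abstract_length Number of body sentences of the abstract.
#' @return Object of class `tagged_sentence`: tokens, a mention table
#'   (`start`, `end`, `label`, `variant`, `canonical`), masked spans, and
#'   the positional metadata.
#' @export
tag_sentence <- function(sentence, query_tf = NULL, lexicon,
                         sentence_index = -1L, abstract_length = 0L) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  tokens <- if (length(sentence) == 1L) tokenize_sentence(sentence)
            else as.character(sentence)
  masked <- mask_abbreviation_longforms(tokens)
  query_canonical <- .resolve_query_tf(query_tf, lexicon)

  idx <- lexicon$index
  mentions <- list()
  n <- length(tokens)
  if (n > 0L && nrow(idx) > 0L) {
    max_len <- max(idx$ntok)
    i <- 1L
    while (i <= n) {
      hit <- NULL
      for (len in seq(min(max_len, n - i + 1L), 1L)) {
        span <- tokens[i:(i + len - 1L)]
        raw <- paste(span, collapse = " ")
        low <- tolower(raw)
        rows <- idx[idx$ntok == len &
                      ((idx$cs & idx$key == raw) |
                       (!idx$cs & idx$key == low)), , drop = FALSE]
        if (nrow(rows) > 0L) {
          # TF dictionary outranks the gene dictionary on equal-length hits
          rows <- rows[order(rows$kind != "TF"), , drop = FALSE]
          hit <- list(start = i, end = i + len - 1L,
                      kind = rows$kind[1L], canonical = rows$canonical[1L],
                      variant = raw)
          break
        }
      }
      if (is.null(hit)) {
        i <- i + 1L
      } else {
        mentions[[length(mentions) + 1L]] <- hit
        i <- hit$end + 1L
      }
    }
  }

  out <- .empty_mentions()
  seen_tf <- FALSE
  for (m in mentions) {
    is_query <- !is.null(query_canonical) && m$kind == "TF" &&
      m$canonical == query_canonical
    if (is_query) {
      if (seen_tf) next  # later occurrences of the query are ignored
      seen_tf <- TRUE
      label <- "TF"
    } else {
      label <- "TG"
    }
    out <- rbind(out, data.frame(
      start = m$start, end = m$end, label = label,
      variant = m$variant, canonical = m$canonical,
      stringsAsFactors = FALSE))
  }

  entity_spans <- lapply(seq_len(nrow(out)),
                         function(k) c(out$start[k], out$end[k]))
  vm <- lexicon$verb_map
  if (length(vm) && n > 0L) {
    for (j in seq_len(n)) {
      low <- tolower(tokens[j])
      if (!(low %in% names(vm))) next
      if (.in_spans(j, masked)) next
      if (.in_spans(j, entity_spans)) next
      out <- rbind(out, data.frame(
        start = j, end = j, label = "KEYVERB",
        variant = low, canonical = unname(vm[[low]]),
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL

  structure(
    list(tokens = tokens, mentions = out,
         sentence_index = as.integer(sentence_index),
         abstract_length = as.integer(abstract_length),
         masked = masked,
         query_tf = query_canonical),
    class = "tagged_sentence"
  )
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat("<tagged_sentence> ", length(x$tokens), " tokens, ",
      nrow(x$mentions), " mentions (index ", x$sentence_index, ")\n", sep = "")
  if (nrow(x$mentions)) print(x$mentions)
  invisible(x)
}

#' Paths to the demonstration lexicon and seed files
#'
#' The package ships a small illustrative lexicon (a handful of TFs, genes
#' and key verbs around the hypoxia response) and a default seed-pattern
#' file; real analyses should supply full user dictionaries.
#'
#' @return Named list of file paths (`tf`, `gene`, `verbs`, `exceptions`,
#'   `seeds`, `corpus`).
#' @export
demo_files <- function() {
  f <- function(x) system.file("extdata", x, package = "generex", mustWork = TRUE)
  list(tf = f("tf_dictionary.tsv"),
       gene = f("gene_dictionary.tsv"),
       verbs = f("key_verbs.tsv"),
       exceptions = f("exception_words.txt"),
       seeds = f("seed_patterns.tsv"),
       corpus = f("demo_corpus.tsv"))
}

#' Load the demonstration lexicon shipped with the package
#'
#' @return A `gene_lexicon` built from [demo_files()].
#' @export
demo_lexicon <- function() {
  p <- demo_files()
  load_lexicons(p$tf, p$gene, p$verbs, p$exceptions, quiet = TRUE)
}
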