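# Wildcard regulation patterns and unsupervised induction.
#
# A regulation pattern is an ordered sequence of items -- the entity
# placeholder "[TF/TG]" or a literal token (a key-verb surface form or a
# preposition) -- with an implicit wildcard between consecutive items. The
# wildcard matches zero or more tokens within one sentence and never crosses
# a sentence boundary. The canonical string joins items with ".*", e.g.
# "[TF/TG].*activation.*of.*[TF/TG]". Every pattern carries exactly two
# entity placeholders and one key-verb literal (a regulation statement needs
# a TF, a TG and an action word), arranged as one of three templates:
#   1: [TF/TG]  keyverb (prep) [TF/TG]
#   2: keyverb (prep) [TF/TG] (prep) [TF/TG]
#   3: [TF/TG] (prep) [TF/TG] (prep) keyverb

.PLACEHOLDER <- "[TF/TG]"

.PREPOSITIONS <- c("of", "by", "with", "to", "in", "on", "for",
                   "through", "via")

#' Prepositions kept literal in patterns
#'
#' Templates mark prepositions optional without enumerating them; this is
#' the closed set the package treats as pattern literals.
#' @return Character vector.
#' @export
pattern_prepositions <- function() .PREPOSITIONS

#' Split a canonical pattern string into its items
#'
#' Items are entity placeholders (`"[TF/TG]"`) or literal tokens; the
#' implicit wildcard between items is not materialized. The bare `TF/TG`
#' spelling is normalized to the bracketed placeholder.
#'
#' @param x Canonical pattern string (or a `regulation_pattern`).
#' @return Character vector of items.
#' @export
pattern_items <- function(x) {
  if (inherits(x, "regulation_pattern")) {
    return(x$items)
  }
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  items <- strsplit(x, ".*", fixed = TRUE)[[1]]
  items <- trimws(items)
  items <- items[nzchar(items)]
  items[items == "TF/TG"] <- .PLACEHOLDER
  items
}

#' Canonicalize a pattern string
#'
#' @param x Pattern string.
#' @return Canonical string with `"[TF/TG]"` placeholders joined by `".*"`.
#' @export
canonical_pattern <- function(x) {
  items <- pattern_items(x)
  if (sum(items == .PLACEHOLDER) != 2L) {
    stop("a regulation pattern needs exactly two entity placeholders: ", x)
  }
  lit <- items != .PLACEHOLDER
  items[lit] <- tolower(items[lit])
  if (!any(lit)) {
    stop("a regulation pattern needs at least one literal: ", x)
  }
  paste(items, collapse = ".*")
}

# Template id from the arrangement of a canonical item sequence:
# leading literal -> 2, trailing literal -> 3, otherwise 1.
.infer_template <- function(pattern) {
  items <- pattern_items(pattern)
  if (items[1L] != .PLACEHOLDER) return(2L)
  if (items[length(items)] != .PLACEHOLDER) return(3L)
  1L
}

#' Build a pattern set
#'
#' A pattern set is a data frame keyed by canonical pattern string with the
#' template id, the raw occurrence frequency and (after
#' [normalize_frequencies()]) the frequency normalized by the set maximum.
#' Duplicate canonical strings are merged by summing frequencies.
#'
#' @param pattern Character vector of pattern strings.
#' @param template Integer template ids (1, 2 or 3); inferred from the
#'   arrangement when missing.
#' @param frequency Non-negative occurrence counts (default 0).
#' @return Object of class `pattern_set` (a data frame with columns
#'   `pattern`, `template`, `frequency`, `norm_frequency`).
#' @export
pattern_set <- function(pattern = character(), template = NULL,
                        frequency = NULL) {
  pattern <- vapply(as.character(pattern), canonical_pattern, "",
                    USE.NAMES = FALSE)
  n <- length(pattern)
  if (is.null(template)) {
    template <- vapply(pattern, .infer_template, integer(1L),
                       USE.NAMES = FALSE)
  }
  if (is.null(frequency)) frequency <- rep(0, n)
  stopifnot(length(template) == n, length(frequency) == n,
            all(frequency >= 0))
  df <- data.frame(pattern = pattern, template = as.integer(template),
                   frequency = as.numeric(frequency),
                   norm_frequency = rep(NA_real_, n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$pattern)) {
    freq <- tapply(df$frequency, df$pattern, sum)
    tmpl <- tapply(df$template, df$pattern, min)
    keys <- names(freq)
    df <- data.frame(pattern = keys,
                     template = as.integer(tmpl[keys]),
                     frequency = as.numeric(freq[keys]),
                     norm_frequency = NA_real_,
                     stringsAsFactors = FALSE)
  }
  df <- df[order(-df$frequency, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pattern_set", "data.frame")
  df
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("<pattern_set> ", nrow(x), " pattern(s)",
      if (nrow(x)) paste0(", max frequency ", max(x$frequency)), "\n",
      sep = "")
  NextMethod()
}

#' Maximal raw frequency of a pattern set
#' @param ps A `pattern_set`.
#' @return Numeric scalar (0 for an empty set).
#' @export
max_pattern_frequency <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  if (nrow(ps) == 0L) 0 else max(ps$frequency)
}

# Is a preposition token usable as a literal at position `pos`?
.literal_prep_at <- function(tagged, pos, lower_excl, upper_excl) {
  if (is.na(pos) || pos <= lower_excl || pos >= upper_excl) return(NA_character_)
  tok <- tolower(tagged$tokens[pos])
  if (!(tok %in% .PREPOSITIONS)) return(NA_character_)
  if (.in_spans(pos, tagged$masked)) return(NA_character_)
  ms <- tagged$mentions
  for (k in seq_len(nrow(ms))) {
    if (pos >= ms$start[k] && pos <= ms$end[k]) return(NA_character_)
  }
  tok
}

#' Extract candidate regulation patterns from a tagged sentence
#'
#' For every pair of entity mentions (TF and TG are interchangeable in the
#' placeholders) and every key-verb mention arranged as one of the three
#' templates, one pattern is emitted: entity mentions become placeholders,
#' the key-verb surface form stays literal, a preposition immediately
#' following the key verb (template 1) or immediately preceding an entity
#' slot or the trailing key verb (templates 2-3) stays literal, and every
#' other intervening token run is absorbed by a wildcard. A sentence can
#' yield several patterns; duplicates within one sentence are emitted once.
#'
#' @param tagged A `tagged_sentence`.
#' @return Data frame with columns `pattern` and `template` (zero rows when
#'   the sentence has fewer than two entities or no key verb).
#' @export
extract_candidate_patterns <- function(tagged) {
  stopifnot(inherits(tagged, "tagged_sentence"))
  ms <- tagged$mentions
  ents <- ms[ms$label %in% c("TF", "TG"), , drop = FALSE]
  kvs <- ms[ms$label == "KEYVERB", , drop = FALSE]
  empty <- data.frame(pattern = character(), template = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(ents) < 2L || nrow(kvs) == 0L) {
    return(empty)
  }
  ents <- ents[order(ents$start), , drop = FALSE]
  out <- empty
  for (i in seq_len(nrow(ents) - 1L)) {
    for (j in seq.int(i + 1L, nrow(ents))) {
      e1 <- ents[i, ]
      e2 <- ents[j, ]
      for (k in seq_len(nrow(kvs))) {
        kv <- kvs[k, ]
        lit <- tolower(kv$variant)
        items <- NULL
        template <- NA_integer_
        if (kv$start > e1$end && kv$end < e2$start) {
          template <- 1L
          prep <- .literal_prep_at(tagged, kv$end + 1L, kv$end, e2$start)
          items <- c(.PLACEHOLDER, lit, prep, .PLACEHOLDER)
        } else if (kv$end < e1$start) {
          template <- 2L
          p1 <- .literal_prep_at(tagged, e1$start - 1L, kv$end, e1$start)
          p2 <- .literal_prep_at(tagged, e2$start - 1L, e1$end, e2$start)
          items <- c(lit, p1, .PLACEHOLDER, p2, .PLACEHOLDER)
        } else if (kv$start > e2$end) {
          template <- 3L
          p1 <- .literal_prep_at(tagged, e2$start - 1L, e1$end, e2$start)
          p2 <- .literal_prep_at(tagged, kv$start - 1L, e2$end, kv$start)
          items <- c(.PLACEHOLDER, p1, .PLACEHOLDER, p2, lit)
        }
        if (is.null(items)) next
        items <- items[!is.na(items)]
        out <- rbind(out, data.frame(
          pattern = paste(items, collapse = ".*"),
          template = template, stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[!duplicated(out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induce unsupervised patterns from training abstracts
#'
#' Tags every title and body sentence of the training corpus, extracts
#' template candidates and counts pattern occurrences across sentences
#' (repeated emission of the same pattern within one sentence counts once).
#' Subset patterns are then merged into their more general forms and
#' frequencies normalized by the set maximum.
#'
#' @param training List of `abstract` objects.
#' @param query_tf Query TF symbol (optional; placeholders do not
#'   distinguish TF from TG during induction).
#' @param lexicon A `gene_lexicon`.
#' @param merge Merge subset/equivalent patterns (default `TRUE`).
#' @param normalize Compute normalized frequencies (default `TRUE`).
#' @return A `pattern_set`.
#' @export
induce_patterns <- function(training, query_tf = NULL, lexicon,
                            merge = TRUE, normalize = TRUE) {
  counts <- new.env(parent = emptyenv())
  templates <- new.env(parent = emptyenv())
  for (a in training) {
    sentences <- character(0)
    indices <- integer(0)
    if (nzchar(a$title)) {
      sentences <- a$title
      indices <- -1L
    }
    if (length(a$body)) {
      sentences <- c(sentences, a$body)
      indices <- c(indices, seq_along(a$body) - 1L)
    }
    for (s in seq_along(sentences)) {
      tg <- tag_sentence(sentences[s], query_tf, lexicon,
                         sentence_index = indices[s],
                         abstract_length = length(a$body))
      cand <- extract_candidate_patterns(tg)
      for (r in seq_len(nrow(cand))) {
        key <- cand$pattern[r]
        counts[[key]] <- (counts[[key]] %||% 0) + 1
        templates[[key]] <- min(templates[[key]] %||% 3L, cand$template[r])
      }
    }
  }
  keys <- ls(counts)
  ps <- pattern_set(keys,
                    template = vapply(keys, function(k) templates[[k]],
                                      integer(1L)),
                    frequency = vapply(keys, function(k) counts[[k]],
                                       numeric(1L)))
  if (merge && nrow(ps) > 1L) ps <- merge_patterns(ps)
  if (normalize && nrow(ps) > 0L) ps <- normalize_frequencies(ps)
  ps
}

#' Is pattern `a` a subpattern of pattern `b`?
#'
#' `a` is a subpattern of `b` when every sentence matched by `a` is matched
#' by `b`: `b`'s items (literals and placeholders) occur, in order, as a
#' subsequence of `a`'s items, with placeholders aligned to placeholders and
#' `a`'s extra literals absorbed by `b`'s wildcards. For example
#' `"[TF/TG].*induced.*by.*[TF/TG]"` is a subpattern of
#' `"[TF/TG].*induced.*[TF/TG]"`. The relation is reflexive and transitive.
#'
#' @param a,b Canonical pattern strings (or `pattern_items()` inputs).
#' @return Logical scalar.
#' @export
is_subpattern <- function(a, b) {
  .items_subseq(pattern_items(a), pattern_items(b))
}

# TRUE when ib is an order-preserving subsequence of ia.
.items_subseq <- function(ia, ib) {
  pos <- 1L
  na <- length(ia)
  for (e in ib) {
    while (pos <= na && ia[pos] != e) pos <- pos + 1L
    if (pos > na) return(FALSE)
    pos <- pos + 1L
  }
  TRUE
}

#' Merge subset and equivalent patterns
#'
#' Every pattern that is a proper subpattern of another is removed and its
#' frequency added to a surviving, more general pattern; when several
#' survivors subsume it, the lexicographically smallest canonical string
#' receives the mass, so total frequency is conserved. Equivalent patterns
#' (identical canonical strings) are already collapsed by the `pattern_set`
#' constructor.
#'
#' @param ps A `pattern_set`.
#' @return A `pattern_set` containing only maximal patterns; normalized
#'   frequencies are reset (call [normalize_frequencies()] afterwards).
#' @export
merge_patterns <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  n <- nrow(ps)
  if (n <= 1L) {
    ps$norm_frequency <- NA_real_
    return(ps)
  }
  items <- lapply(ps$pattern, pattern_items)
  sub <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) sub[i, j] <- .items_subseq(items[[i]], items[[j]])
    }
  }
  # distinct canonical strings cannot subsume each other mutually, so
  # proper subsumption is simply sub[i, j]
  survivor <- vapply(seq_len(n), function(i) !any(sub[i, ]), logical(1L))
  freq <- ps$frequency
  for (i in which(!survivor)) {
    cands <- which(survivor & sub[i, ])
    target <- cands[order(ps$pattern[cands])][1L]
    freq[target] <- freq[target] + freq[i]
  }
  out <- ps[survivor, , drop = FALSE]
  out$frequency <- freq[survivor]
  out$norm_frequency <- NA_real_
  out <- out[order(-out$frequency, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pattern_set", "data.frame")
  out
}

#' Normalize pattern frequencies by the set maximum
#'
#' Each pattern's normalized frequency is its raw frequency divided by the
#' maximal frequency in the set, so values lie in `[0, 1]` and the most
#' frequent pattern scores exactly 1.
#'
#' @param ps A non-empty `pattern_set` with positive maximal frequency.
#' @return The `pattern_set` with `norm_frequency` filled in.
#' @export
normalize_frequencies <- function(ps) {
  stopifnot(inherits(ps, "pattern_set"))
  if (nrow(ps) == 0L) stop("cannot normalize an empty pattern set")
  mx <- max(ps$frequency)
  if (mx <= 0) stop("cannot normalize: maximal frequency is not positive")
  ps$norm_frequency <- ps$frequency / mx
  ps
}

#' Threshold a pattern set on normalized frequency
#'
#' Low-frequency patterns are noisy; keeping only patterns whose normalized
#' frequency reaches `tau` trades recall for precision. The default 0.464
#' corresponds to a raw cut of 700 under a maximal frequency of 1510.
#'
#' @param ps A `pattern_set`.
#' @param tau_normalized Threshold in `[0, 1]` (default `0.464`).
#' @return The filtered `pattern_set`.
#' @export
threshold_patterns <- function(ps, tau_normalized = 0.464) {
  stopifnot(inherits(ps, "pattern_set"),
            tau_normalized >= 0, tau_normalized <= 1)
  if (nrow(ps) == 0L) return(ps)
  if (anyNA(ps$norm_frequency)) ps <- normalize_frequencies(ps)
  out <- ps[ps$norm_frequency >= tau_normalized, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pattern_set", "data.frame")
  out
}

#' Read a pattern file
#'
#' One canonical pattern string per line, optionally followed by
#' `<TAB>frequency` and `<TAB>template`.
#'
#' @param path File path.
#' @return A `pattern_set`.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pat <- vapply(parts, `[`, "", 1L)
  freq <- vapply(parts, function(p) {
    if (length(p) >= 2L) as.numeric(p[[2L]]) else 0
  }, numeric(1L))
  tmpl <- vapply(parts, function(p) {
    if (length(p) >= 3L) as.integer(p[[3L]]) else NA_integer_
  }, integer(1L))
  if (anyNA(tmpl)) tmpl <- NULL
  pattern_set(pat, template = tmpl, frequency = freq)
}

#' Write a pattern set to a file
#'
#' @param ps A `pattern_set`.
#' @param path Output path.
#' @export
write_patterns <- function(ps, path) {
  stopifnot(inherits(ps, "pattern_set"))
  writeLines(paste(ps$pattern, ps$frequency, ps$template, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}
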