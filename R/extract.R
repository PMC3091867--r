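# Pattern matching against tagged sentences, linguistic features and the
# combined-weight ranking of extracted TF-TG sentences.

#' Feature weight configuration
#'
#' The combined weight of an extracted sentence is the sum of the weights of
#' its active features. The distance feature carries weight 4; the remaining
#' split (template-1 match 3.0, title/final position 2.0, minimal entity and
#' verb counts 1.1) is the package default chosen so that a sentence with
#' all four features active scores 10.1. All weights are configurable.
#'
#' @param w_pattern_t1 Weight when the matched pattern has template 1
#'   (template-1 arrangements are the most reliable regulation statements).
#' @param w_position Weight when the sentence is the title or lies in the
#'   final part of the abstract.
#' @param w_distance Weight when fewer than 10 tokens separate the TF and
#'   TG mentions.
#' @param w_counts Weight when the sentence carries exactly one TF, one TG
#'   and one key-verb mention.
#' @return Object of class `weight_config`.
#' @export
weight_config <- function(w_pattern_t1 = 3.0, w_position = 2.0,
                          w_distance = 4.0, w_counts = 1.1) {
  w <- list(w_pattern_t1 = w_pattern_t1, w_position = w_position,
            w_distance = w_distance, w_counts = w_counts)
  stopifnot(all(vapply(w, is.numeric, logical(1L))),
            all(unlist(w) >= 0))
  structure(w, class = "weight_config")
}

#' Match a regulation pattern against a tagged sentence
#'
#' Returns every assignment of the sentence's entity mentions to the
#' pattern's two placeholders such that the pattern's literals occur, in
#' order and case-insensitively, in the wildcard gaps. Literals never match
#' tokens inside abbreviation long-form masks. An assignment binding the
#' query TF and a TG is reported with `tf`/`tg` filled in; assignments
#' binding two TGs are retained with `tf = NA` (they are kept out of the
#' ranked stream).
#'
#' @param tagged A `tagged_sentence`.
#' @param pattern Canonical pattern string.
#' @return Data frame with one row per assignment: `tf`, `tg`,
#'   `e1_canonical`, `e2_canonical` and the mention spans `e1_start`,
#'   `e1_end`, `e2_start`, `e2_end` (placeholder order).
#' @export
match_pattern <- function(tagged, pattern) {
  stopifnot(inherits(tagged, "tagged_sentence"))
  items <- pattern_items(pattern)
  ph <- which(items == .PLACEHOLDER)
  if (length(ph) != 2L) {
    stop("pattern must contain exactly two entity placeholders: ", pattern)
  }
  empty <- data.frame(tf = character(), tg = character(),
                      e1_canonical = character(), e2_canonical = character(),
                      e1_start = integer(), e1_end = integer(),
                      e2_start = integer(), e2_end = integer(),
                      stringsAsFactors = FALSE)
  ms <- tagged$mentions
  ents <- ms[ms$label %in% c("TF", "TG"), , drop = FALSE]
  if (nrow(ents) < 2L) {
    return(empty)
  }
  lits_before <- items[seq_len(ph[1L] - 1L)]
  lits_mid <- if (ph[2L] - ph[1L] > 1L) {
    items[seq.int(ph[1L] + 1L, ph[2L] - 1L)]
  } else character(0)
  lits_after <- if (ph[2L] < length(items)) {
    items[seq.int(ph[2L] + 1L, length(items))]
  } else character(0)

  tokens_lower <- tolower(tagged$tokens)
  n <- length(tokens_lower)
  embeds <- function(lits, lo, hi) {
    if (length(lits) == 0L) return(TRUE)
    if (lo > hi) return(FALSE)
    pos <- lo
    for (lit in tolower(lits)) {
      while (pos <= hi &&
             (tokens_lower[pos] != lit || .in_spans(pos, tagged$masked))) {
        pos <- pos + 1L
      }
      if (pos > hi) return(FALSE)
      pos <- pos + 1L
    }
    TRUE
  }

  out <- empty
  for (i in seq_len(nrow(ents))) {
    for (j in seq_len(nrow(ents))) {
      if (i == j) next
      a <- ents[i, ]
      b <- ents[j, ]
      if (a$end >= b$start) next  # placeholder order follows token order
      if (!embeds(lits_before, 1L, a$start - 1L)) next
      if (!embeds(lits_mid, a$end + 1L, b$start - 1L)) next
      if (!embeds(lits_after, b$end + 1L, n)) next
      labs <- c(a$label, b$label)
      if ("TF" %in% labs) {
        tf <- if (a$label == "TF") a$canonical else b$canonical
        tg <- if (a$label == "TF") b$canonical else a$canonical
      } else {
        tf <- NA_character_
        tg <- NA_character_
      }
      out <- rbind(out, data.frame(
        tf = tf, tg = tg,
        e1_canonical = a$canonical, e2_canonical = b$canonical,
        e1_start = a$start, e1_end = a$end,
        e2_start = b$start, e2_end = b$end,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# Title, or in the last ceiling(n/3) body sentences.
.in_title_or_final <- function(sentence_index, abstract_length) {
  if (sentence_index == -1L) return(TRUE)
  n <- abstract_length
  n > 0L && sentence_index >= n - ceiling(n / 3)
}

#' Compute the ranking features of a pattern match
#'
#' @param match One row of a [match_pattern()] result (TF bound).
#' @param tagged The `tagged_sentence` the match came from.
#' @param template Template id of the matched pattern.
#' @return List with elements `pattern_match_t1`, `in_title_or_final`,
#'   `tf_tg_distance` (tokens strictly between the two bound mentions),
#'   `distance_lt10` and `minimal_counts` (exactly one TF, one TG and one
#'   key-verb mention in the sentence).
#' @export
compute_features <- function(match, tagged, template) {
  stopifnot(inherits(tagged, "tagged_sentence"), nrow(match) == 1L)
  dist <- match$e2_start - match$e1_end - 1L
  labs <- tagged$mentions$label
  list(
    pattern_match_t1 = identical(as.integer(template), 1L),
    in_title_or_final = .in_title_or_final(tagged$sentence_index,
                                           tagged$abstract_length),
    tf_tg_distance = as.integer(dist),
    distance_lt10 = dist < 10L,
    minimal_counts = sum(labs == "TF") == 1L && sum(labs == "TG") == 1L &&
      sum(labs == "KEYVERB") == 1L
  )
}

#' Combined ranking weight of a feature vector
#'
#' The sum of the active features' weights: template-1 pattern match,
#' title/final position, TF-TG distance below 10 tokens, and minimal
#' entity/verb counts. With the default [weight_config()] the score lies in
#' `[0, 10.1]` and the maximum is attained exactly when all four features
#' are active.
#'
#' @param features List as returned by [compute_features()].
#' @param weights A [weight_config()].
#' @return Numeric scalar.
#' @export
combined_weight <- function(features, weights = weight_config()) {
  stopifnot(inherits(weights, "weight_config"))
  weights$w_pattern_t1 * isTRUE(features$pattern_match_t1) +
    weights$w_position * isTRUE(features$in_title_or_final) +
    weights$w_distance * isTRUE(features$distance_lt10) +
    weights$w_counts * isTRUE(features$minimal_counts)
}

.empty_records <- function() {
  df <- data.frame(pmid = character(), sentence_index = integer(),
                   tf = character(), tg = character(),
                   pattern = character(), template = integer(),
                   pattern_frequency = numeric(),
                   pattern_match_t1 = logical(),
                   in_title_or_final = logical(),
                   tf_tg_distance = integer(),
                   distance_lt10 = logical(),
                   minimal_counts = logical(),
                   combined_weight = numeric(),
                   sentence = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("extraction_records", "data.frame")
  df
}

#' Extract and weight TF-TG sentences from a corpus
#'
#' Tags every title and body sentence for the query TF, matches the pattern
#' set, computes the ranking features and keeps, per `(sentence, TG)` pair,
#' the best-scoring match (ties broken by higher normalized pattern
#' frequency, then pattern order). Assignments binding two TGs (the query
#' absent) are collected in the `"tg_tg"` attribute and excluded from
#' ranking.
#'
#' @param corpus List of `abstract` objects.
#' @param query_tf Query TF symbol or synonym.
#' @param patterns A `pattern_set` (typically induced and thresholded).
#' @param lexicon A `gene_lexicon`.
#' @param weights A [weight_config()].
#' @return An `extraction_records` data frame (unranked; see
#'   [rank_records()]).
#' @export
extract_records <- function(corpus, query_tf, patterns, lexicon,
                            weights = weight_config()) {
  stopifnot(inherits(patterns, "pattern_set"))
  records <- list()
  tg_tg <- list()
  norm <- patterns$norm_frequency
  if (length(norm)) norm[is.na(norm)] <- 0
  for (a in corpus) {
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
      tagged <- tag_sentence(sentences[s], query_tf, lexicon,
                             sentence_index = indices[s],
                             abstract_length = length(a$body))
      ms <- tagged$mentions
      if (sum(ms$label %in% c("TF", "TG")) < 2L) next
      best <- list()  # per TG symbol
      for (p in seq_len(nrow(patterns))) {
        mm <- match_pattern(tagged, patterns$pattern[p])
        for (r in seq_len(nrow(mm))) {
          if (is.na(mm$tf[r])) {
            tg_tg[[length(tg_tg) + 1L]] <- data.frame(
              pmid = a$pmid, sentence_index = indices[s],
              gene_a = mm$e1_canonical[r], gene_b = mm$e2_canonical[r],
              pattern = patterns$pattern[p],
              sentence = sentences[s], stringsAsFactors = FALSE)
            next
          }
          f <- compute_features(mm[r, , drop = FALSE], tagged,
                                patterns$template[p])
          w <- combined_weight(f, weights)
          key <- mm$tg[r]
          cur <- best[[key]]
          if (is.null(cur) || w > cur$w ||
              (w == cur$w && norm[p] > cur$pf)) {
            best[[key]] <- list(
              w = w, pf = norm[p],
              row = data.frame(
                pmid = a$pmid, sentence_index = indices[s],
                tf = mm$tf[r], tg = key,
                pattern = patterns$pattern[p],
                template = patterns$template[p],
                pattern_frequency = norm[p],
                pattern_match_t1 = f$pattern_match_t1,
                in_title_or_final = f$in_title_or_final,
                tf_tg_distance = f$tf_tg_distance,
                distance_lt10 = f$distance_lt10,
                minimal_counts = f$minimal_counts,
                combined_weight = w,
                sentence = sentences[s],
                stringsAsFactors = FALSE))
          }
        }
      }
      for (key in names(best)) {
        records[[length(records) + 1L]] <- best[[key]]$row
      }
    }
  }
  out <- if (length(records)) do.call(rbind, records) else .empty_records()
  rownames(out) <- NULL
  class(out) <- c("extraction_records", "data.frame")
  attr(out, "tg_tg") <- if (length(tg_tg)) do.call(rbind, tg_tg) else NULL
  out
}

#' Rank extraction records by combined weight
#'
#' Stable descending sort by combined weight; ties are broken by the
#' matched pattern's normalized frequency, then by input order.
#'
#' @param records An `extraction_records` data frame.
#' @return The records, ranked.
#' @export
rank_records <- function(records) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) == 0L) return(records)
  pf <- records$pattern_frequency
  pf[is.na(pf)] <- 0
  out <- records[order(-records$combined_weight, -pf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-occurrence baseline: TF, key verb and TG in one sentence
#'
#' The baseline judges a sentence relevant when it contains at least one TF
#' mention, one key-verb mention and one target-gene mention. Every
#' pattern-matched sentence with a bound TF also satisfies the baseline,
#' but not conversely: the baseline ignores arrangement and so suffers more
#' false positives.
#'
#' @param tagged A `tagged_sentence`.
#' @return Logical scalar.
#' @export
baseline_tf_kv_tg <- function(tagged) {
  stopifnot(inherits(tagged, "tagged_sentence"))
  labs <- tagged$mentions$label
  any(labs == "TF") && any(labs == "KEYVERB") && any(labs == "TG")
}

#' Run the co-occurrence baseline over a corpus
#'
#' @param corpus List of `abstract` objects.
#' @param query_tf Query TF symbol or synonym.
#' @param lexicon A `gene_lexicon`.
#' @return Data frame with one row per `(sentence, TG)` pair of every
#'   baseline-positive sentence: `pmid`, `sentence_index`, `tf`, `tg`,
#'   `sentence`.
#' @export
baseline_extract <- function(corpus, query_tf, lexicon) {
  rows <- list()
  for (a in corpus) {
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
      tagged <- tag_sentence(sentences[s], query_tf, lexicon,
                             sentence_index = indices[s],
                             abstract_length = length(a$body))
      if (!baseline_tf_kv_tg(tagged)) next
      ms <- tagged$mentions
      tf <- ms$canonical[ms$label == "TF"][1L]
      for (tg in unique(ms$canonical[ms$label == "TG"])) {
        rows[[length(rows) + 1L]] <- data.frame(
          pmid = a$pmid, sentence_index = indices[s],
          tf = tf, tg = tg, sentence = sentences[s],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(pmid = character(), sentence_index = integer(),
               tf = character(), tg = character(), sentence = character(),
               stringsAsFactors = FALSE)
}
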