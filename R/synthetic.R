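# Seeded synthetic corpora with planted regulation sentences and ground
# truth, plus precision/recall scoring of extraction output.

# Filler vocabulary for wildcard gaps and distractor padding; disjoint from
# every dictionary, key-verb form and pattern preposition so ground truth is
# unambiguous (checked against the lexicon at generation time).
.FILLERS <- c("notably", "strongly", "markedly", "cultured", "tissue",
              "samples", "assay", "profile", "robustly", "distinct",
              "broadly", "evidently", "further", "whereas", "overall")

#' Specify a synthetic corpus
#'
#' @param planted Data frame with columns `pattern` (canonical string),
#'   `tf`, `tg` (symbols present in the fixture lexicon) and `count`
#'   (number of sentences to realize, `>= 1`).
#' @param distractor_count Number of distractor sentences.
#' @param distractor_mode `"no_keyverb"` (entities and filler, no action
#'   word: negative for baseline and patterns alike), `"entity_only"`
#'   (TF, gene and a key verb used by no planted pattern: a baseline false
#'   positive that no planted pattern matches) or `"shuffled"` (tokens of a
#'   planted-style sentence permuted).
#' @param title_fraction Share of planted sentences placed in abstract
#'   titles (default 0.2).
#' @param long_gap Plant TF-TG distances of at least 10 tokens instead of
#'   the usual short gaps (for distance-feature testing).
#' @param rng_seed Integer seed; the generated corpus is a deterministic
#'   function of the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(planted, distractor_count = 0L,
                           distractor_mode = c("no_keyverb", "entity_only",
                                               "shuffled"),
                           title_fraction = 0.2, long_gap = FALSE,
                           rng_seed = 1L) {
  distractor_mode <- match.arg(distractor_mode)
  stopifnot(is.data.frame(planted),
            all(c("pattern", "tf", "tg", "count") %in% names(planted)),
            nrow(planted) >= 1L, all(planted$count >= 1L),
            title_fraction >= 0, title_fraction <= 1,
            distractor_count >= 0L)
  planted$pattern <- vapply(planted$pattern, canonical_pattern, "",
                            USE.NAMES = FALSE)
  structure(list(planted = planted,
                 distractor_count = as.integer(distractor_count),
                 distractor_mode = distractor_mode,
                 title_fraction = title_fraction,
                 long_gap = isTRUE(long_gap),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

# Realize one planted pattern: substitute placeholders with the TF/TG
# symbols and fill wildcard gaps with neutral tokens. Gaps between the two
# entity placeholders draw 0-2 fillers (keeping TF-TG distances < 10) and
# 0-6 elsewhere; gaps adjacent to a literal preposition stay empty so that
# re-extraction reproduces the planted canonical string exactly.
.realize_sentence <- function(pattern, tf, tg, long_gap = FALSE) {
  items <- pattern_items(pattern)
  ph <- which(items == .PLACEHOLDER)
  subs <- items
  subs[ph] <- c(tf, tg)
  is_prep <- items %in% .PREPOSITIONS
  tokens <- character(0)
  gap_done <- FALSE
  for (k in seq_along(subs)) {
    if (k > 1L) {
      between_entities <- k > ph[1L] && k <= ph[2L]
      n_fill <- if (long_gap && !gap_done && k == ph[2L]) {
        gap_done <- TRUE
        12L
      } else if (is_prep[k] || is_prep[k - 1L]) {
        0L
      } else if (between_entities) {
        sample(0:2, 1L)
      } else {
        sample(0:6, 1L)
      }
      if (n_fill > 0L) {
        tokens <- c(tokens, sample(.FILLERS, n_fill, replace = TRUE))
      }
    }
    tokens <- c(tokens, subs[k])
  }
  paste0(.capitalize(paste(tokens, collapse = " ")), ".")
}

.reserved_words <- function(lexicon) {
  tolower(c(unlist(lexicon$tf, use.names = FALSE),
            unlist(lexicon$gene, use.names = FALSE),
            unlist(lexicon$verbs, use.names = FALSE),
            .PREPOSITIONS))
}

#' Generate a synthetic corpus with ground truth
#'
#' Realizes each planted pattern `count` times (placeholders substituted by
#' the given TF/TG, wildcards filled with neutral vocabulary), adds
#' distractor sentences according to the mode, assigns a share of the
#' planted sentences to abstract titles and partitions the rest into
#' abstract bodies of 3-8 sentences. Deterministic for a fixed
#' `rng_seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param lexicon A `gene_lexicon`; planted symbols must exist in it.
#' @return List with `corpus` (list of `abstract` objects) and `truth`, a
#'   data frame with one row per sentence (`pmid`, `sentence_index`,
#'   `sentence`, `positive`, `tf`, `tg`) carrying the planted per-pattern
#'   frequencies as attribute `"planted"`.
#' @export
generate_corpus <- function(spec, lexicon) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(lexicon, "gene_lexicon"))
  known <- c(names(lexicon$tf), names(lexicon$gene))
  bad <- setdiff(unique(c(spec$planted$tf, spec$planted$tg)), known)
  if (length(bad)) {
    stop("planted symbols not in the lexicon: ", paste(bad, collapse = ", "))
  }
  if (any(.FILLERS %in% .reserved_words(lexicon))) {
    stop("filler vocabulary collides with the lexicon")
  }
  .with_seed(spec$rng_seed, {
    planted_sent <- list()
    for (r in seq_len(nrow(spec$planted))) {
      row <- spec$planted[r, ]
      for (k in seq_len(row$count)) {
        planted_sent[[length(planted_sent) + 1L]] <- list(
          text = .realize_sentence(row$pattern, row$tf, row$tg,
                                   spec$long_gap),
          tf = row$tf, tg = row$tg, pattern = row$pattern)
      }
    }

    verb_forms <- unlist(lexicon$verbs, use.names = FALSE)
    planted_lits <- tolower(unlist(lapply(spec$planted$pattern,
                                          pattern_items)))
    unused_verbs <- setdiff(verb_forms, planted_lits)
    gene_syms <- names(lexicon$gene)

    distractors <- character(spec$distractor_count)
    for (d in seq_len(spec$distractor_count)) {
      distractors[d] <- switch(
        spec$distractor_mode,
        no_keyverb = {
          ents <- sample(known, sample(1:2, 1L))
          toks <- sample(c(ents, sample(.FILLERS, sample(4:7, 1L),
                                        replace = TRUE)))
          paste0(.capitalize(paste(toks, collapse = " ")), ".")
        },
        entity_only = {
          if (length(unused_verbs) == 0L) {
            stop("entity_only distractors need a key-verb form unused by ",
                 "the planted patterns")
          }
          tfs <- sample(spec$planted$tf, 1L)
          tg <- sample(setdiff(gene_syms, tfs), 1L)
          kv <- sample(unused_verbs, 1L)
          toks <- c(tfs, sample(.FILLERS, sample(1:3, 1L), replace = TRUE),
                    kv, sample(.FILLERS, sample(1:3, 1L), replace = TRUE),
                    tg)
          paste0(.capitalize(paste(toks, collapse = " ")), ".")
        },
        shuffled = {
          row <- spec$planted[sample(nrow(spec$planted), 1L), ]
          s <- .realize_sentence(row$pattern, row$tf, row$tg, spec$long_gap)
          toks <- sample(tokenize_sentence(s))
          paste0(.capitalize(paste(toks, collapse = " ")), ".")
        })
    }

    n_title <- round(spec$title_fraction * length(planted_sent))
    title_ids <- if (n_title > 0L) {
      sample(seq_along(planted_sent), n_title)
    } else integer(0)

    pool <- c(planted_sent[setdiff(seq_along(planted_sent), title_ids)],
              lapply(distractors, function(x) {
                list(text = x, tf = NA_character_, tg = NA_character_,
                     pattern = NA_character_)
              }))
    pool <- if (length(pool)) pool[sample(length(pool))] else pool
    titles <- planted_sent[title_ids]

    corpus <- list()
    truth_rows <- list()
    i_abs <- 0L
    pool_pos <- 1L
    title_pos <- 1L
    while (pool_pos <= length(pool) || title_pos <= length(titles)) {
      i_abs <- i_abs + 1L
      pmid <- sprintf("SYN%05d", i_abs)
      if (title_pos <= length(titles)) {
        tinfo <- titles[[title_pos]]
        title_pos <- title_pos + 1L
      } else {
        tinfo <- list(
          text = .capitalize(paste(sample(.FILLERS, 4L), collapse = " ")),
          tf = NA_character_, tg = NA_character_, pattern = NA_character_)
      }
      m <- min(sample(3:8, 1L), length(pool) - pool_pos + 1L)
      body_info <- if (m > 0L) pool[seq.int(pool_pos, pool_pos + m - 1L)]
                   else list()
      pool_pos <- pool_pos + m
      corpus[[i_abs]] <- abstract(
        pmid, tinfo$text,
        vapply(body_info, function(x) x$text, ""))
      all_info <- c(list(tinfo), body_info)
      idx <- c(-1L, seq_len(m) - 1L)
      for (q in seq_along(all_info)) {
        info <- all_info[[q]]
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          pmid = pmid, sentence_index = idx[q], sentence = info$text,
          positive = !is.na(info$tf), tf = info$tf, tg = info$tg,
          pattern = info$pattern, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    planted_freq <- stats::aggregate(count ~ pattern, data = spec$planted,
                                     FUN = sum)
    names(planted_freq) <- c("pattern", "frequency")
    attr(truth, "planted") <- planted_freq
    list(corpus = corpus, truth = truth)
  })
}

#' Score extraction records against synthetic ground truth
#'
#' Precision, recall and F1 at the `(sentence, TF, TG)` granularity:
#' a record is a true positive when the corresponding truth sentence is a
#' planted regulation statement with the same TF and TG; planted sentences
#' with no matching record are false negatives. Zero denominators yield 0
#' with a warning.
#'
#' @param records An `extraction_records` data frame (or the
#'   [baseline_extract()] output).
#' @param truth The truth data frame from [generate_corpus()].
#' @return Named list: `precision`, `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
score_extraction <- function(records, truth) {
  stopifnot(is.data.frame(records), is.data.frame(truth))
  key <- function(pmid, idx, tf, tg) paste(pmid, idx, tf, tg, sep = "\r")
  pos <- truth[truth$positive, , drop = FALSE]
  truth_keys <- unique(key(pos$pmid, pos$sentence_index, pos$tf, pos$tg))
  rec_keys <- if (nrow(records)) {
    unique(key(records$pmid, records$sentence_index,
               records$tf, records$tg))
  } else character(0)
  tp <- length(intersect(rec_keys, truth_keys))
  fp <- length(setdiff(rec_keys, truth_keys))
  fn <- length(setdiff(truth_keys, rec_keys))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}
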