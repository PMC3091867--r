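test_that("pattern matching binds the query TF and each compatible target gene", {
  tg <- tag_sentence(worked_sentence, "HIF-1", demo_lex)
  mm <- match_pattern(tg, "[TF/TG].*activation.*of.*[TF/TG]")
  expect_true(any(mm$tf == "HIF-1" & mm$tg == "LDHA", na.rm = TRUE))

  lex <- tiny_lexicon()
  none <- match_pattern(tag_sentence("HIF-1 and EPO were measured",
                                     "HIF-1", lex),
                        "[TF/TG].*activates.*[TF/TG]")
  expect_identical(nrow(none), 0L)

  two <- match_pattern(tag_sentence("HIF-1 activation of EPO and VEGF",
                                    "HIF-1", lex),
                       "[TF/TG].*activation.*of.*[TF/TG]")
  two <- two[!is.na(two$tf), ]
  expect_setequal(two$tg, c("EPO", "VEGF"))
})

test_that("assignments binding two target genes are kept out of the ranked stream", {
  lex <- tiny_lexicon()
  tg <- tag_sentence("EPO activation of VEGF was shown", "HIF-1", lex)
  mm <- match_pattern(tg, "[TF/TG].*activation.*of.*[TF/TG]")
  expect_identical(nrow(mm), 1L)
  expect_true(is.na(mm$tf))
  corpus <- list(abstract("1", "", "EPO activation of VEGF was shown."))
  ps <- normalize_frequencies(
    pattern_set("[TF/TG].*activation.*of.*[TF/TG]", frequency = 1))
  rec <- extract_records(corpus, "HIF-1", ps, lex)
  expect_identical(nrow(rec), 0L)
  expect_identical(nrow(attr(rec, "tg_tg")), 1L)
})

test_that("features count tokens between mentions and locate the sentence in the abstract", {
  lex <- tiny_lexicon()
  tg <- tag_sentence("HIF-1 activates EPO", "HIF-1", lex,
                     sentence_index = -1L, abstract_length = 5L)
  mm <- match_pattern(tg, "[TF/TG].*activates.*[TF/TG]")
  f <- compute_features(mm[1, ], tg, template = 1L)
  expect_identical(f$tf_tg_distance, 1L)
  expect_true(f$distance_lt10)
  expect_true(f$in_title_or_final)
  expect_true(f$minimal_counts)
  expect_true(f$pattern_match_t1)

  far <- paste("HIF-1", paste(rep("strongly", 11), collapse = " "),
               "activates EPO")
  tg2 <- tag_sentence(far, "HIF-1", lex, 0L, 9L)
  mm2 <- match_pattern(tg2, "[TF/TG].*activates.*[TF/TG]")
  f2 <- compute_features(mm2[1, ], tg2, 1L)
  expect_identical(f2$tf_tg_distance, 12L)
  expect_false(f2$distance_lt10)

  # last-third rule on a 9-sentence body: index 2 is early, index 8 final
  tg3 <- tag_sentence("HIF-1 activates EPO", "HIF-1", lex, 2L, 9L)
  expect_false(compute_features(
    match_pattern(tg3, "[TF/TG].*activates.*[TF/TG]")[1, ], tg3,
    1L)$in_title_or_final)
  tg4 <- tag_sentence("HIF-1 activates EPO", "HIF-1", lex, 8L, 9L)
  expect_true(compute_features(
    match_pattern(tg4, "[TF/TG].*activates.*[TF/TG]")[1, ], tg4,
    1L)$in_title_or_final)
})

test_that("the combined weight is the sum of active feature weights", {
  w <- weight_config()
  all_on <- list(pattern_match_t1 = TRUE, in_title_or_final = TRUE,
                 tf_tg_distance = 1L, distance_lt10 = TRUE,
                 minimal_counts = TRUE)
  expect_identical(combined_weight(all_on, w), 10.1)
  none <- list(pattern_match_t1 = FALSE, in_title_or_final = FALSE,
               tf_tg_distance = 20L, distance_lt10 = FALSE,
               minimal_counts = FALSE)
  expect_identical(combined_weight(none, w), 0)
  dist_only <- modifyList(none, list(distance_lt10 = TRUE))
  expect_identical(combined_weight(dist_only, w), 4)

  # monotone: activating any feature never lowers the score
  flags <- c("pattern_match_t1", "in_title_or_final", "distance_lt10",
             "minimal_counts")
  for (k in 1:20) {
    f <- stats::setNames(as.list(sample(c(TRUE, FALSE), 4, TRUE)), flags)
    base <- combined_weight(f, w)
    expect_gte(base, 0)
    expect_lte(base, 10.1)
    for (fl in flags[!unlist(f[flags])]) {
      expect_gte(combined_weight(modifyList(f, stats::setNames(list(TRUE), fl)),
                                 w), base)
    }
  }
})

test_that("ranking sorts by weight with frequency tie-break and is stable", {
  rec <- data.frame(
    pmid = as.character(1:4), sentence_index = 0L,
    tf = "HIF-1", tg = c("A", "B", "C", "D"),
    pattern_frequency = c(0.2, 0.4, 0.9, 0.4),
    combined_weight = c(4.0, 10.1, 6.0, 6.0),
    stringsAsFactors = FALSE)
  ranked <- rank_records(rec)
  expect_identical(ranked$tg, c("B", "C", "D", "A"))
  same <- data.frame(pmid = as.character(1:3), sentence_index = 0L,
                     tf = "x", tg = c("A", "B", "C"),
                     pattern_frequency = 0.5, combined_weight = 5,
                     stringsAsFactors = FALSE)
  expect_identical(rank_records(same)$tg, c("A", "B", "C"))
  tie <- data.frame(pmid = as.character(1:2), sentence_index = 0L,
                    tf = "x", tg = c("A", "B"),
                    pattern_frequency = c(0.4, 0.9), combined_weight = 5,
                    stringsAsFactors = FALSE)
  expect_identical(rank_records(tie)$tg, c("B", "A"))
})

test_that("the co-occurrence baseline requires TF, key verb and TG in one sentence", {
  lex <- tiny_lexicon()
  expect_true(baseline_tf_kv_tg(tag_sentence("HIF-1 activates EPO",
                                             "HIF-1", lex)))
  expect_false(baseline_tf_kv_tg(tag_sentence("HIF-1 and EPO were measured",
                                              "HIF-1", lex)))
  masked <- tag_sentence(
    "cAMP response element-binding protein (CREB) and EPO were measured",
    "CREB", lex)
  expect_false(baseline_tf_kv_tg(masked))
})

test_that("every ranked pattern extraction also satisfies the baseline", {
  spec <- synthetic_spec(planted_ten(counts = rep(3, 10)),
                         distractor_count = 40, rng_seed = 5)
  gen <- generate_corpus(spec, demo_lex)
  ps <- induce_patterns(gen$corpus, "HIF-1", demo_lex)
  rec <- extract_records(gen$corpus, "HIF-1", ps, demo_lex)
  expect_gt(nrow(rec), 0L)
  for (r in seq_len(nrow(rec))) {
    tg <- tag_sentence(rec$sentence[r], "HIF-1", demo_lex)
    expect_true(baseline_tf_kv_tg(tg))
  }
})

test_that("one record per sentence and target keeps the best-scoring match", {
  lex <- tiny_lexicon()
  corpus <- list(abstract("1", "HIF-1 activation of EPO was shown."))
  ps <- pattern_set(c("[TF/TG].*activation.*of.*[TF/TG]",
                      "[TF/TG].*activation.*[TF/TG]"),
                    frequency = c(5, 10))
  ps <- normalize_frequencies(ps)
  rec <- extract_records(corpus, "HIF-1", ps, lex)
  expect_identical(nrow(rec), 1L)
  # equal weights (both template 1): the higher-frequency pattern wins
  expect_identical(rec$pattern, "[TF/TG].*activation.*[TF/TG]")
})
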