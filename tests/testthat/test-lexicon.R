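test_that("gene-name normalization removes parenthesized groups and keeps them as variants", {
  expect_identical(
    normalize_gene_name("ATP-binding cassette sub-family A (ABC1), member 4"),
    c("ATP-binding cassette sub-family A, member 4", "ABC1"))
  expect_identical(normalize_gene_name("EPO"), "EPO")
  expect_identical(normalize_gene_name("alpha (A) beta (B) gamma"),
                   c("alpha beta gamma", "A", "B"))
})

test_that("normalization warns on unbalanced parentheses and keeps the orphan literally", {
  expect_warning(out <- normalize_gene_name("ABC (DEF"),
                 "unbalanced")
  expect_identical(out, "ABC (DEF")
})

test_that("normalization conserves non-parenthesized content", {
  char_bag <- function(x) {
    chs <- strsplit(gsub("[[:space:]]", "", paste(x, collapse = "")), "")[[1]]
    sort(chs)
  }
  names <- c("one (two) three", "a(b)c", "x (y z) w (v)",
             "plain name", "lead (A) (B) tail")
  for (nm in names) {
    expect_identical(char_bag(normalize_gene_name(nm)),
                     char_bag(gsub("[()]", "", nm)),
                     info = nm)
  }
})

test_that("lexicon loading filters exception words, expands gene names and merges duplicates", {
  td <- withr::local_tempdir()
  tf <- file.path(td, "tf.tsv")
  gene <- file.path(td, "gene.tsv")
  verbs <- file.path(td, "verbs.tsv")
  exc <- file.path(td, "exc.txt")
  writeLines(c("HIF-1\tHIF-1|HIF1|Cell",
               "AP1\tAP1",
               "AP1\tactivator protein 1"), tf)
  writeLines("ABCA4\tATP-binding cassette sub-family A (ABC1), member 4", gene)
  writeLines("activate\tactivates|activation", verbs)
  writeLines(c("To", "Alpha", "Cell"), exc)
  lex <- load_lexicons(tf, gene, verbs, exc, quiet = TRUE)
  expect_false("Cell" %in% lex$tf[["HIF-1"]])
  expect_true("HIF1" %in% lex$tf[["HIF-1"]])
  expect_setequal(lex$tf[["AP1"]], c("AP1", "activator protein 1"))
  expect_true("ABC1" %in% lex$gene[["ABCA4"]])
  expect_true("ATP-binding cassette sub-family A, member 4" %in%
                lex$gene[["ABCA4"]])
  expect_error(
    load_lexicons(tf, file.path(td, "empty.tsv"), verbs, exc),
    "no such file")
  empty <- file.path(td, "empty.tsv")
  writeLines(character(0), empty)
  expect_error(load_lexicons(tf, empty, verbs, exc, quiet = TRUE), "empty")
})

test_that("a symbol present in both dictionaries resolves through the TF dictionary", {
  lex <- lexicon(tf = list(CBP = c("CBP", "CREB-binding protein")),
                 gene = list(CBPG = "CBP"),
                 verbs = list(activate = "activates"))
  tg <- tag_sentence("CBP activates something", query_tf = NULL, lex)
  ent <- tg$mentions[tg$mentions$label == "TG", ]
  expect_identical(ent$canonical, "CBP")
})

test_that("abbreviation long forms are masked from key-verb matching", {
  toks <- tokenize_sentence(
    "cAMP response element-binding protein ( CREB ) activates X")
  spans <- mask_abbreviation_longforms(toks)
  expect_length(spans, 1L)
  expect_identical(toks[spans[[1]][1]:spans[[1]][2]],
                   c("cAMP", "response", "element-binding", "protein"))
  expect_identical(mask_abbreviation_longforms(
    tokenize_sentence("HIF-1 activates EPO")), list())
  toks2 <- tokenize_sentence(
    "vascular endothelial growth factor ( VEGF ) induction")
  spans2 <- mask_abbreviation_longforms(toks2)
  expect_length(spans2, 1L)
  expect_identical(spans2[[1]], c(1L, 4L))
})

test_that("a masked long-form word is not tagged as a key verb", {
  lex <- tiny_lexicon()
  tg <- tag_sentence(
    "cAMP response element-binding protein (CREB) and EPO were measured",
    query_tf = "CREB", lexicon = lex)
  expect_false(any(tg$mentions$label == "KEYVERB"))
  # without the parenthesized short form, "response" would be an action word
  tg2 <- tag_sentence("The response of EPO was measured",
                      query_tf = "CREB", lexicon = lex)
  expect_true(any(tg2$mentions$label == "KEYVERB"))
})

test_that("tagging the worked hypoxia sentence finds one TF, the target genes and the action word", {
  tg <- tag_sentence(worked_sentence, "HIF-1", demo_lex)
  m <- tg$mentions
  expect_identical(m$canonical[m$label == "TF"], "HIF-1")
  expect_setequal(m$canonical[m$label == "TG"],
                  c("LDHA", "ALDOA", "PGK1", "ENO1"))
  expect_identical(m$variant[m$label == "KEYVERB"], "activation")
})

test_that("tagging yields at most one TF and never tags exception words", {
  lex <- tiny_lexicon()
  sentences <- c(
    "HIF-1 activates EPO and HIF-1 induces VEGF",
    "To the Cell the Alpha HIF1 responds",
    "EPO VEGF LDHA activation",
    "")
  for (s in sentences) {
    tg <- tag_sentence(s, "HIF-1", lex)
    expect_lte(sum(tg$mentions$label == "TF"), 1L)
    expect_false(any(tolower(tg$mentions$variant) %in%
                       c("to", "alpha", "cell")))
    # determinism
    expect_identical(tg$mentions,
                     tag_sentence(s, "HIF-1", lex)$mentions)
  }
  expect_identical(nrow(tag_sentence("", "HIF-1", lex)$mentions), 0L)
})

test_that("short all-caps symbols match case-sensitively, longer names case-insensitively", {
  lex <- lexicon(tf = list(TO = "TO", `HIF-1` = "HIF-1"),
                 gene = list(EPO = "EPO"),
                 verbs = list(activate = "activates"),
                 exceptions = character())
  hit <- function(s) {
    m <- tag_sentence(s, NULL, lex)$mentions
    m$canonical[m$label != "KEYVERB"]
  }
  expect_identical(hit("TO activates EPO"), c("TO", "EPO"))
  expect_false("TO" %in% hit("to activates EPO"))
  expect_false("EPO" %in% hit("Epo levels rose"))
  expect_true("HIF-1" %in% hit("hif-1 activates EPO"))
})

test_that("the query TF mention outranks its own later occurrences and non-query TFs become TGs", {
  lex <- tiny_lexicon()
  tg <- tag_sentence("VHL activates HIF-1 while HIF-1 activates EPO",
                     "HIF-1", lex)
  m <- tg$mentions
  expect_identical(sum(m$label == "TF"), 1L)
  expect_identical(m$start[m$label == "TF"],
                   min(m$start[m$canonical == "HIF-1"]))
  expect_true("VHL" %in% m$canonical[m$label == "TG"])
  expect_error(tag_sentence("x", "NOSUCHTF", lex), "not found")
})

test_that("longest dictionary match wins over shorter embedded variants", {
  lex <- lexicon(tf = list(`HIF-1` = "HIF-1"),
                 gene = list(LDHA = c("LDHA", "lactate dehydrogenase A"),
                             LDH = "lactate dehydrogenase"),
                 verbs = list(activate = "activates"))
  tg <- tag_sentence("HIF-1 activates lactate dehydrogenase A", "HIF-1", lex)
  tgm <- tg$mentions[tg$mentions$label == "TG", ]
  expect_identical(tgm$canonical, "LDHA")
  expect_identical(tgm$end - tgm$start + 1L, 3L)
})
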