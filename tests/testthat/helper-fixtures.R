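# Shared fixtures, built in code.

demo_lex <- demo_lexicon()

tiny_lexicon <- function(exceptions = c("To", "Alpha", "Cell")) {
  lexicon(
    tf = list(
      `HIF-1` = c("HIF-1", "HIF1", "hypoxia-inducible factor-1"),
      CREB = c("CREB", "cAMP response element-binding protein"),
      VHL = "VHL",
      p53 = "p53"),
    gene = list(
      EPO = "EPO",
      VEGF = c("VEGF", "vascular endothelial growth factor"),
      LDHA = c("LDHA", "lactate dehydrogenase A")),
    verbs = list(
      activate = c("activates", "activated", "activation"),
      induce = c("induces", "induced", "induction"),
      respond = c("responds", "response")),
    exceptions = exceptions)
}

# The hypoxia worked sentence (PMID 9748288) used throughout the pattern
# generation examples.
worked_sentence <- paste(
  "Recent reports described a role for the hyposia-inducible factor-1",
  "(HIF-1) in the transcriptional activation of lactate dehydrogenase A,",
  "aldolase-A, phosphoglycerate kinase, and enolase-1 genes.")

make_abstract <- function(pmid, body, title = "") {
  abstract(pmid, title, body)
}

# A planted configuration with pairwise incomparable patterns across the
# three templates; all TF slots use the query HIF-1.
planted_ten <- function(counts = c(50, 40, 30, 25, 21, 17, 12, 8, 5, 1)) {
  data.frame(
    pattern = c("[TF/TG].*activates.*[TF/TG]",
                "[TF/TG].*activation.*of.*[TF/TG]",
                "[TF/TG].*induction.*of.*[TF/TG]",
                "[TF/TG].*regulates.*[TF/TG]",
                "[TF/TG].*represses.*[TF/TG]",
                "induction.*of.*[TF/TG].*by.*[TF/TG]",
                "activation.*of.*[TF/TG].*by.*[TF/TG]",
                "[TF/TG].*binding.*[TF/TG]",
                "[TF/TG].*by.*[TF/TG].*inhibited",
                "suppression.*of.*[TF/TG].*by.*[TF/TG]"),
    tf = "HIF-1",
    tg = c("EPO", "VEGF", "LDHA", "ALDOA", "PGK1",
           "ENO1", "GLUT1", "TERT", "NOS2", "BNIP3"),
    count = counts,
    stringsAsFactors = FALSE)
}

# Brute-force pattern matcher used as an independent oracle: a pattern is
# compiled to a regular expression over space-joined token sentences, with
# placeholders matching the entity tokens of the toy alphabet.
oracle_regex <- function(pattern, entity_tokens) {
  items <- pattern_items(pattern)
  pieces <- vapply(items, function(it) {
    if (it == "[TF/TG]") paste0("(", paste(entity_tokens, collapse = "|"), ")")
    else it
  }, "")
  paste0("(^| )", paste(pieces, collapse = "( \\S+)* "), "( |$)")
}

oracle_matches <- function(pattern, universe, entity_tokens) {
  grepl(oracle_regex(pattern, entity_tokens), universe)
}

# All token sentences of length 1..max_len over the given alphabet, as
# space-joined strings.
sentence_universe <- function(alphabet, max_len) {
  out <- character(0)
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, do.call(paste, grid))
  }
  out
}

# Random pattern over two placeholders and literals from `lits`.
random_pattern <- function(lits, max_extra = 3L) {
  k <- sample(0:max_extra, 1L)
  items <- c("[TF/TG]", "[TF/TG]",
             sample(lits, k, replace = TRUE))
  items <- sample(items)
  if (!any(items != "[TF/TG]")) {
    items <- append(items, sample(lits, 1L), after = 1L)
  }
  paste(items, collapse = ".*")
}
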