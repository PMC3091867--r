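---
title: "Unsupervised regulation patterns: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised regulation patterns: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(generex)
```

This vignette is the package's account of the science it implements: the
assumptions behind dictionary tagging and wildcard patterns, every tunable
parameter with its default and rationale, what the synthetic-corpus
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The model

A regulation statement is assumed to be expressible within a single
sentence as a co-arrangement of a transcription factor (TF), a target gene
(TG) and an *action word* — a key verb such as *activate* or its noun form
*activation*. A **regulation pattern** is an ordered sequence of items:
the entity placeholder `[TF/TG]`, one key-verb literal, and optional
preposition literals. Between consecutive items sits an implicit wildcard
`.*` matching zero or more tokens; wildcards never cross sentence
boundaries. Internally a pattern is exactly this item sequence, which
makes two structural invariants hold by construction: no two adjacent
wildcards, and a canonical string (items joined by `.*`) unique per
pattern. Three templates are admitted, distinguished by the position of
the key verb relative to the two entity slots; only template 1
(entity–verb–entity) carries the pattern-match ranking weight, because
that arrangement is the most reliably a direct regulation statement.

The placeholders deliberately do not distinguish TF from TG: the same
surface pattern describes "X activates Y" for any pair of entities, and
self-regulation is real biology, so direction is recovered at extraction
time from which bound mention is the query. A consequence worth knowing:
a sentence "A activates B" queried with B yields the pair (TF = B,
TG = A). The extraction stage cannot tell regulator from substrate inside
a symmetric arrangement; this mirrors the method's stated inability to
distinguish a second TF from a TG.

## Tagging assumptions

* **Dictionaries, not learned NER.** Entities are recognized by longest
  match against TF and gene dictionaries (canonical symbol plus
  synonyms/aliases). Approved gene names with parenthesized alternate
  symbols are split: `ATP-binding cassette sub-family A (ABC1), member 4`
  becomes the cleaned long name *and* `ABC1`.
* **One TF per sentence.** Mentions matching the query are labeled TF
  (first occurrence only); every other dictionary hit is a TG. Homonyms
  present in both dictionaries resolve through the TF dictionary, since
  the TF plays the central role in the regulatory statement.
* **Exception words** (`To`, `Alpha`, `Cell`, ...) are dictionary names
  identical to common English words and are never tagged. Beyond that
  list, short all-caps symbols (four characters or fewer) match
  case-sensitively; everything else case-insensitively. This keeps `EPO`
  matching while `to`/`To` cannot fire a `TO` entry.
* **Abbreviation masking.** In `long form (SHORT)` constructions the long
  form is located by Schwartz–Hearst-style right-to-left initial-character
  alignment and excluded from key-verb matching, so *response* inside
  `cAMP response element-binding protein (CREB)` is not an action word.
  The method statement names this problem but no algorithm; the
  initial-character alignment is the standard solution and is the
  package's choice. Key verbs are likewise not tagged inside entity
  mentions — a verb-derived word inside a multi-word gene name is part of
  the name.

## Induction, merging, thresholding

Training abstracts are those whose *title* matches a seed pattern — full
pattern matching on the tagged title, not substring search, because seeds
contain placeholders that only tagging can instantiate. From every tagged
sentence, each (entity pair, key verb) arrangement matching a template
emits one pattern; a preposition is kept literal only when directly
adjacent to the key verb (template 1) or immediately preceding the
following slot (templates 2–3), which reproduces the canonical
`[TF/TG].*activation.*of.*[TF/TG]` from the classic hypoxia sentence.
The counting unit is one per (sentence, pattern): repeated emission of
one pattern within a sentence counts once, since the occurrence notion is
per sentence, not per binding.

`is_subpattern(a, b)` decides match-set inclusion symbolically: `b`'s
items must occur in order as a subsequence of `a`'s, placeholders aligned
to placeholders. This is equivalent to semantic inclusion — the minimal
sentence realizing `a` witnesses the converse — and the test suite checks
the equivalence against a brute-force regular-expression oracle over all
token sentences of length ≤ 7 from a four-token alphabet.

Merging removes every pattern properly subsumed by another and adds its
frequency to a surviving, more general pattern. When several incomparable
survivors subsume the same pattern, its mass goes to the survivor with the
lexicographically smallest canonical string: adding it to all of them
would double-count, and the deterministic tie-break keeps total frequency
mass conserved (a property the tests assert on random fixtures).

Parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| preposition set | of, by, with, to, in, on, for, through, via | — | templates mark prepositions optional without listing them; this closed set covers the regulation phrasings |
| normalized threshold `tau` | 0.464 | fraction of max frequency | corresponds to a raw cut of 700 under a maximal frequency of 1510; raising it trades recall for precision |
| max frequency | computed from the pattern set | count | the reported maximal frequency (1,510) exceeds the top printed occurrence (1,452); the package always normalizes by its own computed maximum |
| threshold scope | one global cut | — | whether the three templates were cut separately is unstated; a single cut is simpler and monotone |

## Ranking

Four binary features, weights summing to 10.1 when all are active:
distance weight 4.0 (TF–TG gap < 10 tokens, measured in tokens strictly
between the mention spans — punctuation tokens count), template-1 match
3.0, title-or-final position 2.0, minimal counts 1.1. Only the distance
weight and the 10.1 total are fixed by the method statement; the
3.0/2.0/1.1 split is the package default chosen to reproduce the total,
makes no claim about the ordering of the three unknown weights, and is
fully configurable through `weight_config()`. "Final part of the
abstract" is implemented as the last ⌈n/3⌉ body sentences of an
n-sentence body, the title being index −1. The counts feature is binary
(exactly one TF, one TG, one key verb); no graded form is defined.
A sentence matching several patterns keeps, per (sentence, TG), the
best-scoring match, ties broken by higher normalized pattern frequency —
accumulating weights across patterns would make scores depend on how
redundant the pattern set is. TG–TG assignments (query absent) are
reported in a separate stream and never ranked.

## Networks

`expand_layers()` is a breadth-first expansion: layer 1 is the query's
extracted TG set; extracted TGs found in the TF dictionary become the
next round's queries, four rounds by default. Each symbol is used as a
query at most once (visited set), which guarantees termination on cyclic
corpora — cycles are real (mutual regulation) but are not discussed in
the method statement, so the visited-set rule is the package's choice.
Node layers are minimal over discovery; edge support counts extracted
sentences above a configurable combined-weight floor (default 0, letting
users trade precision for recall), and confidence is support normalized
by the network maximum rather than a raw count, so the strongest edge is
always 1.0 and the high-confidence flag (default cut 0.5) is
corpus-size-independent.

## The synthetic generator

`generate_corpus()` emulates the structure of a pattern-induction
training corpus: planted sentences realize known patterns for known
TF/TG pairs at known counts, mixed with distractors, partitioned into
abstracts of 3–8 sentences with a configurable share of planted sentences
used as titles (default 0.2, echoing that regulation statements
concentrate in titles and final sentences). Wildcard gaps draw filler
tokens from a vocabulary disjoint from all dictionaries, verb forms and
prepositions, so ground truth is unambiguous. Gaps between the two entity
slots draw 0–2 fillers (0–6 elsewhere) keeping every planted TF–TG
distance below 10, and gaps adjacent to a literal preposition stay empty
so re-extraction reproduces the planted canonical string exactly; a
`long_gap` option plants distances ≥ 10 for testing the distance feature.

Distractor modes: `no_keyverb` sentences carry entities and filler but no
action word, so both the co-occurrence baseline and the pattern extractor
reject them; `entity_only` sentences carry a TF, a gene and a key verb
that no planted pattern uses as a literal — a baseline false positive
that leaves pattern-extractor precision at 1.0 (the mode therefore
requires a spare verb in the lexicon and errors otherwise); `shuffled`
permutes a planted-style sentence's tokens and is labeled negative
without any guarantee about accidental matches.

What passing tests on synthetic corpora do **not** show: real abstracts
contain clause-level statements, anaphora, general verbs (*identify*,
*demonstrate*) and relations spanning several sentences, none of which
the generator emulates and all of which the single-sentence pattern model
misses by design. Recovery and perfect precision/recall on planted
corpora validate the machinery, not performance on PubMed.

## Numerical and degenerate-input choices

* Tokenization splits on whitespace and punctuation but keeps hyphenated
  names (`HIF-1`, `element-binding`) whole; parentheses are standalone
  tokens because abbreviation detection needs them.
* Sentence splitting is deterministic: a terminator followed by
  whitespace and an upper-case letter or digit ends a sentence unless it
  is inside parentheses or follows a known abbreviation (`i.e.`, `Fig.`).
* Empty sentences tag to zero mentions; empty training corpora induce an
  empty pattern set; normalizing an empty (or all-zero) set is an error
  rather than a silent NaN.
* Unbalanced parentheses in gene names keep the orphan bracket literally,
  with a warning.
* Equivalent patterns cannot arise as distinct canonical strings (mutual
  subsequence implies equality), so the equivalence collapse reduces to
  the duplicate merge in the `pattern_set` constructor.
* All generator randomness flows through one integer seed; identical
  spec + seed gives byte-identical corpora and downstream results.

## Problem sizes

The shipped test and acceptance workloads use a 10-pattern planted
configuration with counts spanning 1–50 plus 500 distractor sentences
(about 700 sentences over ~130 abstracts), a subpattern oracle over the
~21,800 token sentences of length ≤ 7 on a four-token alphabet with 150
pattern pairs, and four-layer networks on hand-built chain and cycle
corpora. These sizes exercise every code path while keeping the whole
suite under a minute on one core.

## Known limitations

Single-sentence scope; dictionary coverage bounds recall (no species
disambiguation, no database identifier mapping); the demonstration
lexicon is illustrative, not a curated resource; pattern direction is not
resolved inside symmetric arrangements; and reported confidences are
normalized frequencies, not calibrated probabilities.
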