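---
title: "The Influence metric: measuring clause dissemination in treaty corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Influence metric: measuring clause dissemination in treaty corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infmetric)
```

## The model

Bilateral investment treaties are negotiated between exactly two parties,
and their clause language is heavily re-used: a government drafting a new
treaty tends to copy wording from earlier treaties, its own or others'. The
Influence score INF(c) operationalises "country c's clauses are the ones
being copied" as: the total normalised weight of high-similarity documents
in which c is a party.

The pipeline has four stages, each exposed as its own function so
intermediate objects can be inspected:

1. `pairwise_similarities()` — every clause is preprocessed and embedded as
   a TF-IDF vector, w(term, doc) = TF × log(N / DF), with TF the *relative*
   term frequency (occurrences over document length) and DF the number of
   documents containing the term, no smoothing. All N(N−1)/2 unordered
   pairs are scored by cosine similarity.
2. `filter_pairs()` — pairs scoring at least the threshold t are retained
   (inclusive comparison). The M retained pairs reference 2M document
   slots.
3. `doc_weights()` — each distinct retained document is weighted by its
   frequency among the 2M slots divided by 2M; weights sum to 1.
4. `compute_inf()` — a country's score is the sum of the weights of the
   retained documents naming it as a party.

`inf_pipeline()` composes the four stages. Two invariants follow directly
from the construction and are enforced in the test suite: every score lies
in [0, 1], and scores sum to 2 across countries whenever M ≥ 1 (each
document donates its full weight to each of its two distinct parties). A
corpus whose records all share one party is a star network; that hub
receives INF 1 at any threshold retaining a pair, which `detect_star()`
recognises structurally.

Raising the threshold does *not* monotonically raise a given country's
score, although it tends to: dropping a pair removes weight from some
countries and re-normalises the rest, and the test suite carries an
explicit three-treaty counter-example.

## Modelling assumptions worth knowing

* TF as relative frequency vs. raw count is a presentation choice, not a
  modelling one: per-document normalisation rescales each vector by a
  positive constant, so every cosine score — and hence every INF value —
  is identical under either definition. The tests verify this to 1e-12.
* The IDF logarithm base (natural log here) likewise rescales all weights
  of a model by one positive constant and leaves cosine unchanged; it is
  configurable only for presentation of the weights themselves.
* A term occurring in *every* document has IDF 0 and drops out of the
  geometry. When a restricted vocabulary consists solely of such terms,
  both vectors are zero; we define cosine as 1 for two zero vectors (over
  the modelled terms the documents are indistinguishable) and 0 when
  exactly one norm vanishes. This convention is part of the metric's
  contract, not a numerical accident.
* Threshold comparison is inclusive (score ≥ t) and performed after
  rounding scores to 12 decimal places, so ties at the threshold behave
  identically across platforms.
* Word order is ignored entirely. For legal text this is a real
  limitation: two clauses with identical vocabulary but different operative
  structure score 1.

## Preprocessing

`preprocess_config()` controls the pipeline: lower-casing (default on),
stop-word removal (default on, using the standard Snowball English list,
overridable or replaceable by a one-token-per-line file), and reduction
(default `"lemma"`). Tokenisation keeps internal ASCII hyphens —
"health-related" is one token — and strips all other punctuation.

The reducers are deliberately lightweight, deterministic rule systems
written for this package: the stemmer strips the longest matching
derivational suffix (so "investigation" and "investigator" meet at
"investig"), and the lemmatiser undoes common inflections with
consonant-doubling and elided-"e" repair ("caring" → "care", "policies" →
"policy"). They are not part-of-speech aware, and their exact outputs
differ from other stemmer implementations; nothing downstream depends on a
particular reducer, and reduction can be switched off. Textbook TF-IDF hand
calculations that count every surface word ("should" included) are
reproduced with `preprocess_config(remove_stopwords = FALSE,
reduction = "none")`; the default configuration is the one intended for
real corpora.

## Threshold selection

`select_threshold(pairs, ceiling)` implements retrospective selection: the
returned t is the smallest observed score with at least `ceiling` of all
scores at or below it — the empirical quantile of the score multiset. On
the 90 evenly spaced scores 0.01…0.90 a 60% ceiling returns 0.54. The
choice of ceiling is the analyst's: high ceilings retain few, very similar
pairs and zero out most countries; low ceilings blur genuinely different
similarity levels into one retained group. Similarity-score distributions
of real treaty corpora are strongly right-skewed, which is why ceilings of
0.8–0.95 are the practically useful range; `summarize_similarities()` and
`export_similarity_histogram()` expose the distribution for this decision.

## The synthetic generator

Real treaty corpora with curated health-safeguard categories are not
freely redistributable, so validation runs on generated corpora with
planted structure. `generate_diffusion_corpus()` emulates the *shape* of
such a corpus: 555 dyadic records over 1959–2021 by default, category
labels drawn with weights 419/263/22 across defensive/neutral/offensive
and multiclass records at rates 125/555 (two labels) and 12/555 (three),
clauses built from a closed vocabulary of treaty-flavoured tokens.
Clause re-use is explicit: with probability `copy_prob` (default 0.5,
a realistic middle ground between fresh drafting and verbatim copying)
a new treaty copies an earlier clause — one of the hub's, when a hub is
planted — and mutates each token with probability `mutation_rate`
(default 0.05, light editorial drift). Copying treaties always include
the hub as a party, making the hub the constructive ground-truth top
influencer; over 20 seeded runs at `copy_prob = 0.9` the pipeline
recovers the hub as argmax-INF in at least 90% of runs, and at
`copy_prob = 1, mutation_rate = 0` the hub's score is exactly 1.

What the generator does **not** emulate: real legal language (clauses are
token bags, so passing tests say nothing about lemmatiser quality on real
prose), correlation between categories and clause content, country-specific
treaty propensities, or the exact similarity distribution of any real
corpus — only its qualitative right skew at low `copy_prob`.
`generate_star_corpus()` is the minimal special case: one hub, identical
(or lightly mutated) clauses, used for the exact INF = 1 property.

## Numerical and design choices

* Degenerate inputs: an empty corpus, a clause that preprocesses to zero
  tokens, and a vocabulary term absent from the corpus are errors naming
  the offending record; M = 0 is *not* an error — it yields an all-zero
  influence table with a warning, so period/category sweeps can report
  "insufficient data" cells without aborting.
* Countries appearing only in unretained documents are reported with
  INF 0 rather than omitted, keeping rankings comparable across runs.
* Reports are sorted (descending INF, ties lexical by country), scores are
  written at fixed precision, and all generator randomness flows from an
  explicit seed, so identical inputs give byte-identical outputs.
* Sample (n−1) standard deviation and linear-interpolation quantiles are
  used in `summarize_similarities()`.
* Party names are opaque strings: "BLEU" (the Belgium–Luxembourg Economic
  Union) is one party, and no name normalisation is attempted.
* Multiclass records are included in *each* of their categories when
  slicing with `filter_corpus()`; the full clause text is reused for every
  class.

## Problem sizes

The validation suite runs entirely at desk scale, chosen to exercise every
code path while keeping the whole suite in seconds: exhaustive brute-force
equivalence on 200 random corpora of up to 10 documents, hub recovery on
20 corpora of 30 treaties, and one 419-document generated corpus
(87,571 pairs) for the pair-count arithmetic. The pairwise stage uses a
sparse document–term matrix and a single cross-product, so corpora in the
low thousands of documents remain comfortable on a laptop.

## Known limitations

TF-IDF cosine ignores word order and semantics; near-paraphrases with
different vocabulary score low, and boilerplate-heavy clauses score high.
Scores are sensitive to document length through TF normalisation. The
metric itself has no uncertainty quantification — it is a descriptive
weighting of an observed similarity graph, and comparisons between
countries with few treaties should be read accordingly.
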