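---
title: "Mining literature for drug-repurposing candidates with litrx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining literature for drug-repurposing candidates with litrx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litrx)
```

## The problem

Rare diseases accumulate too little dedicated research for conventional drug
discovery, but their pathomechanisms often overlap with well-studied
conditions. litrx implements a literature-based discovery pipeline in the
Swanson ABC tradition: starting from a disease of interest (the *query
phrase*, e.g. chronic thromboembolic pulmonary hypertension, CTEPH), it maps
what the literature already says about the disease, identifies an *associated
disease* with a much larger literature (e.g. venous thrombosis), and then
ranks every drug mentioned in either literature by how semantically close it
is to the query disease — surfacing drugs that have never been studied for it
but travel in the same semantic circles. The end of the pipeline is
deliberately sceptical: a module of cohort-outcome statistics for checking a
candidate against real-world data, because a semantically plausible candidate
can still be harmful in practice.

## The pipeline and its model

### Term identification

Abstracts are normalized (sentence split, tokenized, lowercased, lemmatized)
and every distinct token is classified into one of three categories:

* **drug compounds** — tokens matching a United States Adopted Names (USAN)
  approved stem at its declared position (prefix, suffix or infix: "-mab",
  "-ciguat", "guan-", ...), provided the token is *not* an ordinary English
  dictionary word. The dictionary veto suppresses stem collisions ("guano"
  matches "guan-" but is prose, not pharmacology).
* **clinical features** — tokens ending in a medical-glossary suffix
  ("-osis", "-emia", "-pnea", ...).
* **other** — everything else.

The categories partition the vocabulary; a token matching both a stem and a
suffix goes to the drug category by default (stems are the more specific
signal; configurable). Tokens shorter than 5 characters are never classified
specially — short tokens collide with stems far too often for the match to
carry information. Stem-position semantics: a prefix stem must start the
token, a suffix stem must end it, and an infix stem must occur strictly
inside (a match touching either boundary does not count, otherwise every
infix would subsume a prefix and suffix reading).

### Interval-weighted TF-IDF

Term relevance is scored by a TF-IDF variant that is computed per
publication-time interval (calendar years by default):

$$\mathrm{score}(t, I) \;=\; tf_{I}(t) \cdot \frac{1}{df(t)} \cdot
\frac{D_{\mathrm{corpus}}}{D_{I}}$$

where $tf_I$ is the term's share of all tokens in interval $I$, $df$ is the
share of corpus documents containing the term, and $D_{\mathrm{corpus}}/D_I$
rescales for interval size. The inverse document frequency enters as a *raw
reciprocal*, not the classical logarithm — the formula is implemented
literally as printed above, and the log variant is available behind
`variant = "log"` for comparison. The corpus-wide score is defined as the
single-interval reduction of the same formula (the whole corpus as one
interval, so the $D$ ratio is 1 and the score is $tf/df$); that makes the
corpus-wide and interval-weighted scores one formula and one code path.
Documents with no parsable publication year join no interval — the interval
score needs an interval document count — but still count corpus-wide.
Intervals with zero documents are simply absent.

### Disease-term mining

Candidate disease terms are frequent n-grams flanking clinical-feature
tokens: for every feature occurrence, every contiguous window of 2–5 tokens
that contains the occurrence and fits inside the sentence is collected, and
windows with corpus frequency strictly greater than 5 survive. Two readings
of "flanking" were possible — windows centered on the feature, or all
windows containing it. We emit *all* windows (configurable downstream by
filtering), because real disease terms frequently have the feature at the
window edge ("thrombosis pulmonary"). Windows never cross sentence
boundaries: flanks should be syntactic neighbours. Counting is per
occurrence, so one abstract can contribute many counts — the ranking is a
corpus-wide term frequency, not a document frequency.

### Embedding association

A skip-gram word-embedding model with negative sampling is trained on the
*merged* sentence sequences of both corpora. Tokens that share contexts get
nearby vectors, which is what lets a *bridging term* — one that co-occurs
with a drug in one literature and with the query disease in the other —
pull a drug and a disease together even though they never co-occur
themselves. Every classified drug token that survives the vocabulary floor
is scored by cosine similarity to a user-chosen *prediction term* (a single
token, typically the disease abbreviation; a phrase-to-abbreviation
replacement is applied during normalization when configured). Drugs are
split into **direct** associations (the drug occurs in the query corpus)
and **indirect** associations (it does not) — the indirect list is the
repurposing shortlist. A user-supplied property list (e.g. known pro-/
anti-thrombotic drugs) is joined by exact lemma match only; no fuzzy
matching, since a silent mislabel is worse than a missing label. The
direction of a pharmacological effect (inducing vs. inhibiting) is *not*
inferred — that needs human curation — so the package surfaces ranks and
labels, never conclusions.

Hyperparameter defaults are 200 dimensions, window 8, minimum count 5,
5 epochs, 5 negative samples, following the materials-science
literature-mining precedent this class of pipeline adapts. None of these is
critical to the package's contracts; the tests and the acceptance runs use
smaller dimensionalities (25–50) because the synthetic corpora have
vocabularies of a few hundred types, where 200 dimensions would be badly
overparameterized. The trainer is single-threaded with a private xorshift
RNG, so a fixed seed gives bit-identical vectors across runs and platforms
— reproducibility is worth more here than multicore speed, and corpora of a
few thousand abstracts train in seconds.

### Cohort-outcome statistics

The validation module reproduces the standard epidemiological toolkit for a
2×2 cohort comparison: risks, risk difference, risk ratio, odds ratio,
Kaplan–Meier curves, the one-degree-of-freedom log-rank test and an
observed/expected hazard ratio. Two conventions matter and are pinned by
test: the risk-difference **confidence interval uses the unpooled Wald
standard error** while the **z statistic uses the pooled proportion** —
that pairing (standard in epidemiology software) reproduces a published
reference table from its raw counts, simultaneously matching the printed CI
and z. The 95% quantile is `qnorm(0.975)` = 1.959964, not 1.96. P-values
are also offered formatted to three decimals with a "0.000" floor, as
clinical tables print them. Zero cells are flagged rather than
continuity-corrected: a silent +0.5 changes the estimate, and the caller
should decide. Kaplan–Meier and the log-rank statistic are computed through
the `survival` package; the package's own tests verify them against
hand-tabulated product-limit and O−E computations on small datasets. The
hazard ratio is the Mantel–Haenszel-style O/E ratio
$(O_1/E_1)/(O_2/E_2)$ with a log-scale CI using
$\sqrt{1/E_1 + 1/E_2}$; a Cox model with covariates is out of scope.

## The synthetic-data generator

Offline testability comes from a seeded corpus generator
(`synthetic_spec()` / `generate_corpus()`) that emulates the *statistical*
structure the pipeline assumes, not real prose:

* documents carry years from a configurable range (2010–2024 by default);
* a background vocabulary of pronounceable consonant-vowel strings, each
  checked to be a fixed point of the lemmatizer, dictionary-disjoint, and
  classified "other" by the shipped lexicon;
* drug tokens composed from USAN stems and feature tokens composed from
  medical suffixes, so the classifier can recover exactly the planted set;
* sentence-level topic mixing: each sentence is background prose, a
  drug-context sentence, or a disease-context sentence carrying the
  prediction term. Each drug-context sentence draws its drug uniformly from
  the background and bridged drugs together, so every candidate drug has
  the same expected corpus frequency — an earlier design that gave bridged
  drugs their own topic also gave them higher frequency, and embedding
  similarity tracks frequency strongly enough to confound the bridge
  signal entirely;
* `bridging_strength` is the probability that a prediction-term or
  bridged-drug sentence also carries bridge tokens. Bridged drugs never
  share a sentence with the prediction term, so at strength 0 they are
  statistically indistinguishable from background drugs, and at high
  strength they are connected only through second-order co-occurrence —
  exactly the mechanism the embedding is supposed to exploit.

Default generator conditions used by the recovery checks: 2,000 documents,
4–8 sentences each, 300 background types, 20 background + 5 bridged + 5
direct drugs, 12 bridge tokens, bridging strength 0.9 against a 0.0 null.
The recovery criterion is deliberately strict — *all* bridged drugs must
beat the median background similarity — which makes the null a
$\approx 0.5^5$ coin-flip event, so "passes in ≥9/10 seeds at 0.9, fails in
≥9/10 at 0.0" separates signal from artifact.

What the generator does **not** emulate: grammar, topical drift over years,
multi-word drug names, abbreviation ambiguity, negation, and the heavy-
tailed vocabulary of real abstracts. Passing the synthetic checks therefore
shows the machinery is correct and sensitive to planted structure; it does
not show that any particular real corpus will yield clinically meaningful
candidates, which is why the pipeline ends at ranked tables for human
review.

Cohort and survival simulators (`generate_cohort()`,
`generate_survival()`) draw binomial tables and exponential event times
with uniform random censoring truncated at a horizon; they calibrate the
statistics module (null log-rank rejection ≈ 5%, RR CI coverage ≈ 95%).

## Numerical and design choices

* **Lemmatizer.** Rule-based: a small irregular-form table plus ordered
  suffix rules (Greco-Latin "-oses"→"-osis" before the generic plural
  strip; "-ed"/"-ing" stripped with Porter-style stem repair). A light
  part-of-speech guess (tokens in "-ed"/"-ing" are treated as verbs,
  everything else as noun) replaces a statistical tagger. The rules are
  approximate on purpose — determinism and idempotence (re-normalizing
  normalized text is a no-op, tested) matter more downstream than perfect
  lemmas, because classification and scoring operate on whole tokens.
* **Stop-words** are retained by default: the inverse document frequency
  already down-weights them for scoring, and removing them is only an
  option (`remove_stopwords`) for embedding training.
* **Punctuation** tokens are dropped; intra-word hyphens are preserved
  ("anti-thrombotic" is one token) because stem and suffix matching operate
  on whole tokens; numerals pass through but are never classified.
* **Tie-breaks** are total and documented: rankings order by score then
  lexicographically; n-grams by frequency, then shorter length, then text.
  Every output is therefore byte-stable under a fixed seed (tested
  end-to-end).
* **Degenerate inputs** return empty results or flagged NA values, never
  silent guesses: empty abstracts yield zero tokens, a term absent from the
  corpus scores 0 (the reciprocal-df guard), zero cells flag the odds
  ratio, an event-free dataset gives log-rank p = 1.
* **Problem sizes.** The test suite and acceptance script run the embedding
  checks at 2,000 synthetic documents with 25–50 dimensions and the
  calibration checks at 500–1,000 replicates; these sizes give stable
  pass/fail behaviour at desk scale while the full-size defaults remain
  available through the configuration surface.

## Known limitations

* Single-token drug terms only: multi-word names ("factor xa inhibitor")
  are not detected, matching the single-token lexicon approach.
* The shipped lexicon files are compact snapshots meant to be replaced for
  production use; corpus-dependent counts obtained with them (how many
  drugs a given corpus yields, their exact scores) depend on the snapshot
  and on the retrieval date of the corpus, and are not stable quantities.
* The rule-based lemmatizer will mangle some irregular English; its errors
  are deterministic and harmless to the contracts, but a corpus with heavy
  morphological variation would benefit from swapping in a full
  lemmatizer upstream and feeding pre-normalized text.
* PubMed fetching depends on the Entrez service and is date-dependent by
  nature; fetched corpora should be committed as JSONL so analyses rerun
  offline.

## A small worked example

```{r example}
lex <- default_lexicon()
g <- generate_corpus(synthetic_spec(n_docs = 80, seed = 42), lex)
docs <- normalize_corpus(g$corpus)
cls <- classify_corpus_terms(docs, lex)
tab <- build_term_score_table(docs)
head(rank_terms(tab, cls, "drug_compound", top_k = 5))

ct <- contingency_table(n1 = 453, x1 = 139, n2 = 453, x2 = 67)
risk_analysis(ct)
```
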