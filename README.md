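# litrx

Literature-based discovery of drug-repurposing candidates from publication
abstracts, with the cohort statistics to vet them against real-world data.

litrx is aimed at researchers working on diseases whose own literature is too
small to mine directly — typically rare diseases. It implements a
Swanson-style ABC pipeline over PubMed abstracts:

1. **Term identification.** Abstracts are normalized (sentence split,
   tokenized, lemmatized) and each token is classified as a *drug compound*
   (matches a USAN approved stem such as `-mab`, `-ciguat`, `guan-`, and is
   absent from an English dictionary), a *clinical feature* (ends in a
   medical suffix such as `-osis`, `-emia`, `-pnea`), or neither.
2. **Interval-weighted TF-IDF ranking.** Terms are scored per
   publication-year interval as

   ```
   score(t, I) = tf_I(t) · (1 / df(t)) · (D_corpus / D_I)
   ```

   with a raw reciprocal document frequency; the corpus-wide score is the
   single-interval reduction `tf/df`. This promotes terms that concentrate
   in few documents and highlights newly emerging drugs interval by
   interval.
3. **Disease-term mining.** Frequent n-grams (length 2–5, corpus frequency
   strictly > 5) flanking clinical-feature tokens propose disease terms; the
   user picks an *associated disease* with a large literature from this
   table.
4. **Embedding association.** A skip-gram word2vec model (negative
   sampling) is trained on the merged query + associated corpora; every
   drug term is ranked by cosine similarity to a user-chosen *prediction
   term* and split into **direct** associations (drug already occurs in the
   query-disease corpus) and **indirect** associations (it does not — the
   repurposing candidates), optionally labeled from a user-supplied drug
   property list.
5. **Outcome statistics.** For vetting a candidate against cohort data:
   risks, risk difference (unpooled Wald CI, pooled z), risk ratio, odds
   ratio, Kaplan–Meier curves, log-rank test, and an O/E hazard ratio.

A seeded synthetic-corpus generator with a ground-truth manifest makes the
whole pipeline testable offline, including recovery of planted *bridging*
structure — drugs that never co-occur with the disease but share bridge
terms with it.

## Worked example

Cohort statistics from a published 2×2 comparison (453 patients per arm,
139 vs 67 deaths):

```r
library(litrx)
ct <- contingency_table(n1 = 453, x1 = 139, n2 = 453, x2 = 67)
risk_analysis(ct)
#>           measure  estimate  conf_low conf_high       z            p p_formatted
#> 1    risk_cohort1 0.3068433        NA        NA      NA           NA        <NA>
#> 2    risk_cohort2 0.1479029        NA        NA      NA           NA        <NA>
#> 3 risk_difference 0.1589404 0.1053461 0.2125346 5.70708 1.149307e-08       0.000
#> 4      risk_ratio 2.0746269 1.5983808 2.6927729      NA           NA        <NA>
#> 5      odds_ratio 2.5503375 1.8383648 3.5380471      NA           NA        <NA>
```

Read: the exposed cohort died at 30.7% vs 14.8%, an absolute excess of
15.9 percentage points (95% CI 10.5–21.3, z = 5.707, p < 0.001), risk ratio
2.07, odds ratio 2.55.

The mining pipeline on a synthetic corpus with planted structure:

```r
lex <- default_lexicon()
g <- generate_corpus(synthetic_spec(n_docs = 80, seed = 42), lex)
docs <- normalize_corpus(g$corpus)
cls <- classify_corpus_terms(docs, lex)
tab <- build_term_score_table(docs)
rank_terms(tab, cls, "drug_compound", top_k = 3)
#>        term      score
#> 1 pabaxaban 0.02016129
#> 2   bibamab 0.01881720
#> 3 dibaarone 0.01843318
```

(Synthetic drug names; scores are corpus-wide TF-IDF. On a real corpus the
same call ranks actual medications.) The full flow — ranking tables,
disease-term n-grams, association report — is orchestrated by
`run_rank_stage()` / `run_predict_stage()` or the CLI in `inst/cli/litrx`:

```sh
litrx rank --corpus cteph.jsonl --out-dir results/
litrx predict --query-corpus cteph.jsonl --assoc-corpus vt.jsonl \
      --prediction-term cteph --properties thrombotic_drugs.csv
litrx stats2x2 --n1 453 --x1 139 --n2 453 --x2 67
```

Corpora are JSON Lines (`doc_id`, `year`, `title`, `abstract`), fetched live
with `fetch_pubmed()` or supplied as files; nothing but `fetch_pubmed()`
touches the network.

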