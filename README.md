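# emovoc

Scoring of **active emotion vocabularies** in natural text.

People differ not only in *how often* they write about emotions but in *how
many different* emotion words they spontaneously use. That diversity — the
active emotion vocabulary — is a distinct signal from emotional tone:
frequency-based word counting gives a text that repeats "sad" ten times the
same score as a text using ten different negative emotion words, although
the two texts say very different things about their authors. `emovoc` is
for researchers in computational psycholinguistics and mental-health text
analysis who want to quantify that diversity per document, validate it
against covariates, and stress-test the whole pipeline on synthetic corpora
with known ground truth.

## The statistic

For a document of *N* tokens, the emotion-vocabulary rate is

```
EV = (# unique emotion words / N) × 100
```

where "unique" is counted at the **lemma-group** level: inflectional
variants (*sad*, *sadly*, *sadness*) count as one word. EV is computed
separately for negative and positive words, and for the emotion families
*sadness*, *fear/anxiety*, *anger*, and *undifferentiated negative* (words
like *awful*, *terrible*, *bad*). Supporting metrics include:

- **Frequency-based category rates** — percentage of tokens (repeats
  counted) in a category: emotional tone, cognitive-processing words,
  I-words, we-words, illness, affiliation, achievement, leisure.
- **Type/token ratio (TTR)** — types over tokens as a percentage; the
  open-class variant (function words and emotion words excluded) serves as
  a general-vocabulary proxy.
- **Document screening** — at least 100 tokens and 70% of tokens
  identifiable against a coverage vocabulary.
- **Validation machinery** — Pearson and partial correlations (via
  residualization) with bootstrap standard errors and 95% bias-corrected
  and accelerated (BCa) confidence intervals; split-half and test–retest
  reliability across a corpus.
- **Synthetic corpora** — authors with latent active-lexicon sizes,
  emission rates, Zipf-skewed word reuse, and planted covariate links, so
  every stage can be checked against known parameters.

The packaged dictionary (92 negative / 53 positive lemma headwords, with
inflected surface forms and prefix wildcards) is a synthetic demonstration
lexicon; every function accepts a user dictionary in a simple TSV format
(`pattern  valence  family  lemma_group`).

## Worked example

```r
library(emovoc)

doc <- tokenize("he was so angry at me, but sadly there was nothing I could do")
ev_score(doc, ev_lexicon(), "negative")
#> [1] 14.28571
```

The sentence has 14 tokens and two unique negative emotion words (*angry*
and *sadly*, the latter collapsing to the lemma group *sad*), so EV =
2/14 × 100 = 14.29. The family split shows one sadness word and one anger
word:

```r
round(family_ev_scores(doc, ev_lexicon()), 2)
#>                   sadness                      fear                     anger
#>                      7.14                      0.00                      7.14
#> undifferentiated_negative                  positive
#>                      0.00                      0.00
```

A full pipeline run on a simulated corpus, ending in the partial
correlation between negative EV and a planted "distress" covariate while
controlling for general vocabulary and emotional tone:

```r
sim <- simulate_corpus(sim_config(n_authors = 200), seed = 42)
cs <- score_corpus(sim$corpus)
cs
#> <corpus_scores: of 200 documents, 200 produced analyzable texts (0 excluded);
#>  lexicon emovoc-synthetic v1, config 256dfc9d>

cor_ci(as.data.frame(cs$scores), "neg_ev", "distress",
       controls = c("open_class_ttr", "rate_negative_tone",
                    "rate_positive_tone"),
       n_boot = 2000, seed = 1)
#> partial r(neg_ev, distress | open_class_ttr, rate_negative_tone,
#>  rate_positive_tone) = 0.396 (SE 0.058), 95% BCa CI [0.267, 0.497],
#>  n = 200, p = 8.63e-09
```

The generator planted a positive link from each author's latent negative
lexicon size to distress; the pipeline recovers it with a confidence
interval well clear of zero, over and above tone and verbal diversity.

Command-line wrappers live in `scripts/emovoc_cli.R`
(`score`, `reliability`, `correlate`, `simulate`).

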