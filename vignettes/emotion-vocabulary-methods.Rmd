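---
title: "Measuring active emotion vocabularies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring active emotion vocabularies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emovoc)
```

## The measurement model

`emovoc` quantifies the *diversity* of emotion language in a document.
Standard closed-vocabulary word counting is frequency-based: a category
score is the percentage of tokens that fall in the category, so reusing
one emotion word ten times scores the same as using ten different ones.
The emotion-vocabulary (EV) rate instead counts *unique* emotion words,
collapsed to lemma groups, per 100 tokens:

$$\mathrm{EV} = \frac{\#\,\text{unique emotion lemma groups}}{\text{token count}} \times 100$$

Dividing by length removes the mechanical advantage longer texts have at
accumulating distinct words; the result is a rate, not a raw vocabulary
count, and it assumes documents long enough for a rate to be stable —
hence the screening step below. EV is computed with negative words,
positive words, or one of four negative families (sadness, fear/anxiety,
anger, undifferentiated negative) in the numerator; the denominator is
always the full token count.

Three auxiliary per-document metrics support validation:

- frequency-based **category rates** (tone, cognitive processing,
  I-words, we-words, illness, affiliation, achievement, leisure) — the
  repeats-counted counterpart of EV;
- the **type/token ratio** as a general-vocabulary proxy, in a raw form
  (all tokens) and an open-class form that drops function words and all
  emotion-lexicon matches from numerator and denominator;
- **screening**: a document is analyzable when it has at least
  `min_tokens` tokens (default 100) and at least `min_coverage`
  (default 0.70) of them are identifiable, i.e. present in a coverage
  vocabulary.

## The dictionary and its conventions

Lemma collapsing is encoded *in the dictionary*, not by a stemmer: each
entry carries a `lemma_group`, and uniqueness is counted over groups.
This makes the collapsing auditable — the mapping is data, not an
algorithm whose behaviour shifts with its implementation. Entries are
literal tokens or prefix wildcards (`furi*` matches *furious*,
*furiously*); literals beat wildcards, and among wildcards the longest
prefix wins, deterministic tie-breaks that make matching order-free. A
pattern may belong to one valence and one family only; conflicts are
load-time errors rather than silently tie-broken at match time.

The packaged dictionary is a synthetic demonstration lexicon of words
that *name* emotional states (rather than affectively tinged topic words)
organised as 92 negative and 53 positive lemma headwords. The counts
refer to lemma groups — the headword convention — with inflected surface
forms and wildcards as additional rows inside each group. It is intended
for demonstration, testing, and method development; substantive studies
should supply their own validated dictionary via `read_lexicon()`, which
accepts a four-column TSV.

## Tokenization

The worked examples constrain the tokenizer: the sentence
*"he was so angry at me, but sadly there was nothing I could do"* must
yield 14 tokens and *"A horse! A horse! My Kingdom for a horse!"* nine.
The conventions adopted: Unicode case folding; curly apostrophes
normalised to ASCII; hyphens and dashes split compounds (maximising
dictionary matches); internal apostrophes kept, so contractions are
single tokens; tokens without a letter (bare numbers) dropped.
Tokenization is idempotent on its own output, which the tests verify.

## Correlation machinery

Validation analyses correlate EV with covariates. Partial correlations
residualize both variables on the controls (least squares with
intercept) and correlate the residuals; rank-deficient control sets are
an error naming the collinear column, and rows with missing values are
dropped listwise per analysis. Interval estimates use the bias-corrected
and accelerated (BCa) bootstrap, resampling documents/authors:

- the bias-correction factor $z_0$ is the normal quantile of the
  fraction of replicates below the point estimate (ties counted half);
- the acceleration $a$ uses the standard jackknife skewness formula
  $a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})$ with
  $d_i = \bar{t}_{(\cdot)} - t_{(i)}$ — the literature admits several
  acceleration estimators; the leave-one-out jackknife is the common
  default and is what the `boot` package's BCa interval uses, which the
  tests cross-check against;
- interval endpoints are order statistics of the bootstrap distribution
  at the adjusted levels (quantile type 6);
- resamples on which the statistic is undefined (e.g. a constant column
  after resampling) are redrawn and counted; more than 1% of replicates
  needing redraw aborts the analysis, since at that point the resampling
  distribution no longer reflects the data;
- everything is deterministic given the seed.

Defaults: 2000 replicates (the `study1` preset); the `study2` preset
uses 500, the conventional economy at very large sample sizes.
Two-tailed p-values from the t transformation of r (df = n − 2 −
#controls) are reported alongside the intervals. The bootstrap's
calibration is checked empirically in the acceptance tests: nominal 95%
intervals for a correlation of 0.3 at n = 200 must cover between 92% and
97.5% of 1000 simulation repeats.

## Reliability

Split-half reliability splits each document's token stream at its
midpoint (token index; entry boundaries are not assumed to exist),
scores each half, and correlates the halves across documents. By default
each half is re-screened against the full inclusion criteria — a half
failing the 100-token minimum is not a trustworthy measurement — with a
config switch (`rescreen_halves = FALSE`) for corpora of shorter
documents. Test–retest joins two waves of scores on document/author id
and correlates matched pairs, logging unmatched ids.

## The synthetic corpus generator

The generator exists so that every pipeline stage can be validated
without access to any real corpus. Each author has latent parameters:
active-subset sizes `k_neg`, `k_pos` (how many lemma groups the author
ever uses), emission probabilities `p_emit_neg`, `p_emit_pos` (per-token
chance of an emotion word), a target length (`verbosity`, tokens), and a
Zipf exponent governing within-subset reuse — modelling least-effort
reuse of the most habitual words. Each token position emits a negative
emotion word, a positive one, or a filler content word; emotion
emissions pick a lemma group Zipf-weighted within the author's subset,
then a uniform inflected surface form. Covariates are linear links on
the standardized latent sizes plus Gaussian noise (default: `distress`
on `k_neg` and `wellbeing` on `k_pos`, slope 0.5, unit noise — a
moderate, recoverable association).

Defaults are calibrated to emulate stream-of-consciousness-essay
conditions: lengths of roughly 600 ± 200 tokens, emission probabilities
uniform on 0.5–4.5% (negative) and 1.5–5.5% (positive) so that
frequency-based tone rates average near 2.5% and 3.5% with realistic
between-author spread, and small active subsets (1–8 groups per valence)
so unique-word rates land near half a percent of tokens — the regime in
which active emotion vocabularies are small relative to the dictionary.

What the generator deliberately does **not** emulate: syntax, topic
structure, polysemy (every emitted lexicon word is genuinely
"emotional", whereas real text contains *blue* or *like* in non-emotional
senses), spelling variation, and document-internal drift (emissions are
i.i.d. across positions, so split halves differ only by sampling noise).
Passing the synthetic recovery tests therefore shows the pipeline's
arithmetic and statistical machinery are sound — it does not show that
the packaged demonstration dictionary is a validated instrument for real
populations.

## Validation problem sizes

The acceptance-style tests run at sizes chosen to make sampling noise
small relative to the effects checked: oracle equivalence of all metrics
on 100 simulated documents of ~150 tokens; bootstrap coverage over 1000
repeats at n = 200 with 1000 replicates per interval; split-half limits
at 40 (mirrored halves) and 500 (independent halves) documents;
parameter recovery at 500 authors; end-to-end sign recovery of the
planted distress link at 1000 authors with 2000 bootstrap replicates.

## Known limitations

- EV is length-normalised but not length-independent in small samples:
  below ~100 tokens the unique-word count is dominated by Poisson noise,
  which is why the screening default is 100.
- Dictionary matching is context-free; ironic, negated ("not happy"), or
  quoted emotion words count the same as sincere ones.
- The open-class TTR depends on the function-word list; swapping lists
  changes its level (though typically not its rank order across
  documents).
- BCa intervals are known to undercover slightly for correlations at
  small n; the calibration test bounds this at the sizes used.
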