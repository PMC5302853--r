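---
title: "Caloric scoring of region-labelled text: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Caloric scoring of region-labelled text: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textcal)
```

## The instrument

`textcal` estimates the "caloric content" of large region-labelled text
corpora — the kind of signal used in digital epidemiology, where what a
population posts about food and physical activity correlates with its
health outcomes. Two curated lexicons drive the measurement:

* a **food lexicon** mapping phrases ("pizza", "cake with frosting") to
  lemmas and to kilocalories per 100 g of the food, and
* an **activity lexicon** mapping phrases ("running", "watching tv") to
  lemmas and to Metabolic Equivalents of Task (METs). One MET is
  1 kcal·kg⁻¹·h⁻¹, so a MET value is converted to kcal per hour by
  multiplying with a reference body mass, 80.7 kg by default (an average
  adult weight); `met_to_kcal_per_hour(8, 80.7)` is 645.6 kcal/h.

A *lemma* groups categorically equivalent phrases under one caloric score,
so equality of scores within a lemma is enforced as a hard validation error
rather than averaged away: if two phrases in one lemma disagree, the
lexicon file is wrong.

For a text $T$ with lemma usage distribution $p(s\mid T)$ (counts
normalized within a side), the caloric input and output are
score-weighted means,

$$C_{\mathrm{in}}(T) = \sum_{s \in S_{\mathrm{in}}} C_{\mathrm{in}}(s)\,
p(s\mid T), \qquad
C_{\mathrm{out}}(T) = \sum_{s \in S_{\mathrm{out}}} C_{\mathrm{out}}(s)\,
p(s\mid T),$$

and two composites compare them: the **caloric ratio**
$C_{\mathrm{rat}} = C_{\mathrm{out}} / C_{\mathrm{in}}$ (purely relative;
the value 1 is not meaningful, since 100 g of food and one hour of
activity are arbitrary units) and the **caloric difference**
$C_{\mathrm{diff}}(\alpha) = \alpha C_{\mathrm{out}} -
(1-\alpha) C_{\mathrm{in}}$ with $\alpha \in [0,1]$. Both scores are convex
combinations of lemma scores, so each is bounded by its side's extreme
scores and is invariant to scaling all counts in a region — corpus volume
per region does not leak into the indices.

Two ways of choosing $\alpha$ are provided. `tune_alpha_mean_match()`
solves $\alpha \langle C_{\mathrm{out}}\rangle = (1-\alpha)\langle
C_{\mathrm{in}}\rangle$ over unweighted regional means, which makes the
regional mean of $C_{\mathrm{diff}}(\alpha)$ exactly zero; regions are
weighted equally, matching the equal-weight convention used for the pooled
reference text below. `tune_alpha_to_indicator()` instead grid-searches
the $\alpha$ maximizing $|\rho_s|$ against a chosen indicator (say,
diabetes rates), turning the instrument into a tunable estimator. Because
Spearman correlation depends only on ranks, $|\rho_s|$ is piecewise
constant in $\alpha$ and an exact grid (default step 0.001, ties to the
smallest $\alpha$) is deterministic and as good as continuous
optimization.

A note on a sign convention: the difference is sometimes written with a
plus sign between the two terms in secondary sources; this package uses
the subtractive form above throughout, which is the form that makes
mean-matching zero the regional mean.

## Phrase extraction by serial partitioning

Counting lexicon phrases naively overcounts: "apple" inside "apple of my
eye" is not a food mention. The package therefore segments every clause
into non-overlapping multiword cells and counts a lexicon phrase only when
a cell *exactly equals* it.

Messages are NFKC-normalized, lowercased, stripped of user mentions,
hashtags and URLs, and split into clauses at sentence punctuation
(`. ! ? ; :`); residual punctuation is trimmed from token edges and
symbol-only tokens (emoji) are dropped. Lowercasing and the
mention/hashtag/URL exclusions follow standard social-media preprocessing;
the remaining normalization choices are fixed here for determinism.

Two corpus-level statistics drive the segmentation:

**Random-partition frequency** $f(s)$: the expected number of times $s$
occurs as a cell when every internal gap of a clause of length $L$
independently receives a boundary with probability $\tfrac12$ and clause
edges are always boundaries. A single occurrence of an $\ell$-token phrase
spanning positions $i..j$ contributes
$(\tfrac12)^{\ell-1}(\tfrac12)^{[i>1]}(\tfrac12)^{[j<L]}$, and $f(s)$
sums over occurrences. The closed form is verified in the test suite
against exhaustive enumeration of all $2^{L-1}$ boundary configurations
(to $10^{-12}$ on random clauses up to length 10).

**Context-local likelihood** $L(s)$: an $\ell$-token phrase belongs to
$\ell$ one-wildcard contexts (token $k$ replaced by a wildcard; "new york
city" belongs to `* york city`, `new * city`, `new york *`). For a context
$C$, $P(s\mid C) = f(s) / \sum_{t\in C} f(t)$, and
$L(s) = \min_C P(s\mid C)$ — the likelihood in the phrase's most prevalent
context. $L$ is zero on the empty phrase, on unobserved phrases, and
beyond the length cap. Only the minimum value matters downstream, so no
tie-break among contexts is needed. The cap defaults to `max_len = 5`
tokens: curated lexicon phrases rarely exceed four tokens ("talking on
the phone"), and the cap bounds the statistics tables.

`serial_partition()` then walks a clause left to right, growing the
current phrase by the next token while $L$ **strictly** increases and
flushing it as a cell otherwise (ties flush — the strictness is part of
the algorithm's definition, and the canonical four-copy "new york city"
corpus partitions as `[(new york), (city)]` because $L$ saturates at 1).
Statistics are built in one pass over the whole corpus and partitioning
runs in a second pass, since $f$ and $L$ are corpus-level functions; the
batch partitioner (`partition_corpus()`) performs the greedy walk for all
clauses simultaneously with vectorized likelihood lookups.

Lemma counts (`count_lexicon_lemmas()`) keep only cells exactly equal to a
lexicon phrase, aggregate to lemmas per region, and drop lemmas whose
corpus-wide count is below `min_count = 5` — phrases seen four or fewer
times carry no stable signal. Regions with no matched phrase on a side are
excluded from profiles with a warning, as the weighted mean is undefined
on empty support.

## Phrase shifts

Why does one region score differently from the rest? With a reference
text — by default the equal-weight pool of all regional distributions,
$p_{\mathrm{ref}} = \frac1R \sum_r p(\cdot\mid T_r)$ — the difference
decomposes exactly over lemmas:

$$C(T_{\mathrm{comp}}) - C(T_{\mathrm{ref}}) = \sum_s
\left[C(s) - C_{\mathrm{ref}}\right]
\left[p(s\mid T_{\mathrm{comp}}) - p(s\mid T_{\mathrm{ref}})\right],$$

where centring by $C_{\mathrm{ref}}$ changes nothing (both distributions
sum to one) but makes each term interpretable. Contributions are
normalized to percentages,

$$\delta C(s) = 100\,\frac{[C(s) - C_{\mathrm{ref}}]\,
[p_{\mathrm{comp}}(s) - p_{\mathrm{ref}}(s)]}
{|C_{\mathrm{comp}} - C_{\mathrm{ref}}|},$$

so that $\sum_s \delta C(s) = \pm 100$, positive when the comparison
scores above the reference. The absolute value in the denominator is what
produces the signed total; a signed denominator would collapse every
comparison to $+100$. Each term is labelled by two signs — whether the
lemma's score is above (`+`) or below (`-`) the reference score, and
whether it is used more (`up`) or less (`down`) than in the reference —
giving four categories whose totals partition the net. Exact-zero terms
are dropped: they carry no sign information. Comparisons with
$C_{\mathrm{comp}} = C_{\mathrm{ref}}$ are rejected as degenerate.

The "most distinguishing" lemma of a region (`distinguishing_lemma()`) is
the largest-magnitude term among those used *more* than the reference and
aligned with the net shift — the phrase whose increased usage most moves
the region away from the average. Restricting to increased-usage terms is
a design choice: decreased usage of an opposite-signed phrase moves a
score equally but does not name anything the region actively talks about.

## Correlations with indicator tables

`correlation_table()` tests every caloric measure against every indicator
column (regions aligned by name, missing cells dropped pairwise) with
Spearman's $\rho_s$, computed as the Pearson correlation of average ranks
with a two-sided p-value from the $t$ approximation on $n-2$ degrees of
freedom — standard at panel sizes around 49 regions. All measure ×
indicator tests form **one** Benjamini–Hochberg family by default (the
appropriate correction when the whole table is reported together);
per-measure families are available via `family = "per_measure"`. Rows are
sorted by ascending q-value for $C_{\mathrm{rat}}$ and flagged at
q < 0.01 and q < 0.05. A Pearson coefficient with OLS slope
(`pearson_fit()`) is provided for scatter-plot annotation.

## The synthetic-data generator

Real inputs for this class of instrument — tens of millions of geotagged
messages plus curated lexicons of ~1,400 food and ~13,400 activity
phrases — are external data. The generator produces structurally faithful
stand-ins at desk scale so every stage is testable against known ground
truth:

* `make_fixture_lexicons()` draws food scores on [20, 600] kcal/100 g and
  METs on [0.95, 14] (realistic database ranges), includes 2–4-token
  phrases with tokens disjoint across entries, and names a decoy idiom
  ("apple of my eye") sharing a token with a lexicon phrase but absent
  from the lexicon.
* `plant_usage_profiles()` plants a caloric gradient: region $r$'s lemma
  weights are $\propto \exp(\beta_r z(\mathrm{score}))$ with $\beta_r$
  running linearly across regions, giving a known ordering of planted mean
  scores.
* `simulate_corpus()` emits, per message, a filler clause (vocabulary
  disjoint from all lexicon tokens) plus one food and one activity phrase
  drawn from the region's multinomials, each as its own
  punctuation-delimited clause, mimicking the short-burst style of
  social-media mentions. It returns the exact per-region lemma counts it
  planted.
* `simulate_indicators()` builds indicator columns as
  `slope * measure + N(0, noise_sd)` plus independent null columns, for
  power and false-discovery calibration.

One subtlety is worth recording. Under strict-growth greedy segmentation a
multiword phrase only coheres when its prefixes occur with *varied*
continuations; if a prefix is already the unique member of its contexts,
$L$ saturates at 1 and the phrase splits (exactly as "new york city"
does). Natural language supplies this variation through shared vocabulary;
a synthetic corpus must plant it. The generator therefore follows a
multi-token phrase, occasionally, with a "false start" clause — the
phrase's prefix plus a junk continuation token — at rates 0.3, 0.1, 0.05
for prefix lengths 1, 2, 3. These rates make $L$ strictly increasing along
every planted phrase (the inequalities reduce to the rate of the longer
prefix's companions being sufficiently below that of the shorter's), so
each planted emission is recovered as exactly one cell and pipeline counts
equal the generator's truth exactly — which is what allows the suite to
assert exact count agreement and a zero decoy contribution rather than
approximate recovery.

What the generator does **not** emulate: Zipfian vocabulary growth,
spelling variation, sarcasm and polysemy ("running" a bath), regional
dialect, bot traffic, or volume imbalance between regions. Passing tests
on synthetic corpora therefore demonstrate the correctness of the
machinery — segmentation, counting, scoring, decomposition, correlation —
not the field validity of the indices on real social media, which depends
on lexicon curation quality.

## Study sizes and numerical choices

The test suite fixes these problem sizes as its study conditions: the
end-to-end recovery run uses 10 regions × 20,000 messages (planted
ordering recovered with Kendall $\tau \ge 0.9$; empirical usage within
total-variation distance 0.02 of the planted multinomials at that count);
correlation calibration uses 49-region panels — 100 replicates for
recovery of a planted $\rho_s \approx 0.8$ link (noise level set through
the bivariate-normal relation $\rho_p = 2\sin(\pi\rho_s/6)$) and 1,000
replicates of pure-noise indicators for BH false-discovery control; the
shift normalization identity is exercised on 1,000 random comparisons at
tolerance $10^{-9}$; the partition-frequency oracle enumerates all
boundary configurations for clauses up to length 10.

Other defaults: body mass 80.7 kg (overridable per run for sensitivity
analysis); `max_len` 5 tokens; `min_count` 5; $\alpha$ grid step 0.001;
shift reports print the top 23 terms (full tables are always stored).
Ties are resolved deterministically everywhere — lexicographic lemma
order in argmax selections and rankings, smallest $\alpha$ in grid
search — so identical inputs give identical outputs.

## Limitations

Scores are naive equivalences (100 g per food mention, one hour per
activity mention), so absolute values are not meaningful — only
comparisons between regions scored with the same lexicons. The caloric
ratio inherits the dynamic ranges of its parts; no rescaling of either
side is attempted. Correlation against indicators is observational:
nothing here supports causal readings, and indicator tables mix sources
whose region coverage differs (handled by pairwise deletion, not
imputation). The activity-side lemmatization of real lexicons involves
judgment calls that cannot be reproduced from files alone; lemma
assignments are consumed as given.
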