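# textcal

Caloric scoring of region-labelled text corpora.

`textcal` is an instrument for digital epidemiology: it gauges the
"caloric content" of what large populations write — for example geotagged
social-media streams labelled by state — and turns it into comparable
regional health indices. It is aimed at computational social scientists
and public-health researchers who have (a) a corpus of short messages with
region labels, (b) a curated food lexicon (phrase → lemma → kcal per
100 g) and an activity lexicon (phrase → lemma → MET), and (c) tables of
regional health/well-being indicators to validate or tune against.

## The model

For a text $T$ with lemma usage distribution $p(s\mid T)$, the package
computes score-weighted means on each side,

```
C_in(T)  = Σ_s C_in(s)  p(s|T)        [kcal per 100 g]
C_out(T) = Σ_s C_out(s) p(s|T)        [kcal per hour, MET × 80.7 kg]
```

and the composites `C_rat = C_out / C_in` (relative index; 1 is not
meaningful) and `C_diff(α) = α·C_out − (1−α)·C_in`, with `α` chosen by
mean-matching (regional mean of `C_diff` becomes exactly 0) or by
maximizing |Spearman ρ| against a target indicator.

Phrases are not counted by substring matching. Every clause is segmented
by **serial partitioning** — a greedy left-to-right algorithm that grows a
phrase while its context-local likelihood strictly increases, where the
likelihood is built from random-partition phrase frequencies `f(s)` and
one-wildcard context pools — and a lexicon phrase is counted only when a
partition cell *exactly* equals it. "apple" inside "apple of my eye"
contributes nothing.

Regional differences are explained with **phrase shifts**: the difference
between a region and the equal-weight pooled reference decomposes exactly
into per-lemma percentage contributions `δC(s)` summing to ±100, each
classified by score sign (+/−) and usage direction (↑/↓). Indices are
correlated against indicator tables with Spearman's ρ and
Benjamini–Hochberg q-values across the whole measure × indicator family.

A synthetic-data module generates fixture lexicons, corpora with planted
per-region usage multinomials (plus decoy idioms), and indicator tables
with planted monotone links, so the entire pipeline is testable against
exact ground truth without any external download.

## Worked example

```r
library(textcal)

fx   <- make_fixture_lexicons(20, 20, seed = 42)
prof <- plant_usage_profiles(fx$food, fx$activity, n_regions = 5,
                             messages = 2000, seed = 42)
sim  <- simulate_corpus(prof, fx$food, fx$activity, seed = 42,
                        decoy = fx$decoy, decoy_rate = 0.02)
cal  <- calorimeter(sim$corpus, fx$food, fx$activity)
cal
```

```
<calorimeter: 10000 messages, 33944 clauses, 5 regions, alpha = 0.366>
  region     C_in    C_out    C_rat    C_diff n_in n_out
1    R01 181.5284 347.5701 1.914686 12.329047 2000  2000
2    R02 233.2170 422.4940 1.811592  7.030290 2000  2000
3    R03 320.1242 537.2054 1.678116 -6.005445 2000  2000
4    R04 399.3996 672.2831 1.683234 -6.743570 2000  2000
5    R05 474.2123 802.0216 1.691271 -6.610322 2000  2000
```

The generator planted a caloric gradient across the five regions, and the
recovered `C_in`/`C_out` rise monotonically with it; each region's 2000
food draws all survive extraction (`n_in`). `alpha = 0.366` is the
mean-matched mixing weight, so `C_diff` averages zero across regions.
Why does R01 score low on activity calories? Decompose it:

```r
region_shift(cal, "R01", side = "output", top = 5)
```

```
<phrase_shift side=output 'R01' vs reference: net -100%, C 347.57 vs 556.31>
category totals (%): +up +0.00, -down +0.50, +down -48.97, -up -51.53
     lemma      delta category
1   ACT_TV -25.746503      -up
2 ACT_L010 -16.391175    +down
3 ACT_L011 -14.218201    +down
4 ACT_L007 -13.485072    +down
```

R01 sits 100% below the pooled reference, roughly half from talking more
about low-expenditure activities (−↑, e.g. the TV lemma) and half from
talking less about high-expenditure ones (+↓). Correlating against an
indicator table (here with one planted link and two null columns):

```r
ind <- simulate_indicators(cal$profiles,
  links = data.frame(indicator = "inactivity_pct", measure = "C_rat",
                     slope = -5, noise_sd = 0.5),
  n_null = 2, seed = 42)
correlation_table(cal$profiles, ind)
```

ranks indicators by ascending q for `C_rat` (the planted `inactivity_pct`
comes out first with ρ = −0.8 at n = 5; nothing is significant at such a
tiny panel, which is the correct behaviour of the BH correction).

A thin command-line front end over the same functions ships in
`inst/cli/textcal.R` (`simulate` and `score` subcommands, JSONL corpora
in, TSV profiles/shift JSON out). Small example lexicons are in
`inst/extdata/`.

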