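---
title: "Quantifying acute-period elevations in passively sensed smartphone language"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acute-period elevations in passively sensed smartphone language}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Passive smartphone sensing captures every keystroke an enrolled participant
types, in any app, as timestamped input events. For adolescents at high risk
of suicidal thoughts and behaviors, the days immediately before a
suicide-related hospitalization are a window in which language may change in
detectable ways: more suicide-related vocabulary, more negative sentiment,
more negative self-reference. `acutelang` implements the full measurement
chain for this setting:

1. **ingest** — segment keyboard input events into *text entries*, redact
   PII-shaped spans, and read/write the JSONL/CSV entry formats;
2. **NLP signals** — label each entry for suicide-related language (a lexicon
   engine), sentiment (a pluggable scorer with a deterministic rule-based
   default), and negative self-reference (first-person pronoun rule);
3. **topics** — assign each entry to one of ten seeded topics by cosine
   similarity, or to an outlier class;
4. **windows** — aggregate labels to daily proportions, center each series on
   the person's whole-study mean, split the pre-hospitalization month into an
   acute period (days $-10..0$) and a baseline period (days $-30..-11$), and
   compute the window-length sensitivity curve $R_w$;
5. **correspondence** — align clinician-coded day-level event timelines with
   days of elevated NLP signal.

Because raw participant text from such studies cannot be shared, the package
also includes a first-class synthetic-data generator with known ground truth.
Every downstream stage is validated against it.

## The window-ratio statistic

For a participant with daily entry counts $n_d$ and flagged-entry counts
$x_d$ (for one metric, e.g. suicide-related language), the pooled frequency
over a set $S$ of days is $f(S) = \sum_{d \in S} x_d / \sum_{d \in S} n_d$.
With Day 0 the hospitalization day, the acute window of length $w$ is
$W_w = \{-(w-1), \dots, 0\}$ — it *includes* Day 0, so $w$ counts calendar
days. The within-person window ratio is

$$R_w = \frac{f(W_w)}{f(\text{entire study})}, \qquad w = 1, \dots, 30,$$

with $R_w = 1$ meaning the acute window matches the person's typical level.
The curve $w \mapsto R_w$ is the window-length sensitivity analysis: a signal
concentrated in the last days before admission produces a curve that is high
at small $w$ and decays toward 1. At the group level the pooled $(w, R_w)$
points are smoothed with loess (tricube-weighted local *linear* regression,
span 0.75 by default, pointwise bands from the fit's standard errors).

Two frequency estimators are implemented because published descriptions are
usually silent on the choice: the default is entry-weighted pooling (total
flags over total entries, robust to low-entry days); the alternative is the
unweighted mean of daily proportions (`method = "day_mean"`). Both are
exposed everywhere a frequency is computed, and `pooling_discrepancy()`
reports their difference as a diagnostic whenever daily volumes vary.

### Conventions that had to be fixed

Several day-counting conventions are stated loosely in the literature; the
package fixes them explicitly and makes each configurable:

- **Acute period**: day indices $-A..0$ with $A = 10$, i.e. eleven day-slots
  including the admission day. The baseline is $-30..-(A+1)$. A participant
  enrolled fewer than 30 days before admission gets a truncated or empty
  baseline, not an error.
- **Civil dates**: an entry belongs to the local calendar date of its
  timestamp; post-midnight typing belongs to the new date. Timestamps are
  carried as zone-free local clock times, so no DST arithmetic applies.
- **Time-of-day bins**: half-open bins midnight 00–06, morning 06–12,
  afternoon 12–18, evening 18–24; configurable since the bins are
  conventionally named but rarely defined.
- **Weekend**: Saturday and Sunday (US convention).
- **Missing days** (zero entries) are never imputed: they carry no value, are
  excluded from every mean, and render as blanks.

## The labelers

**Lexicon engine.** A lexicon combines four pattern classes — single-token
keywords, slang terms, multi-word phrases, and emoji. Matching case-folds and
tokenizes on unicode word boundaries (contractions stay single tokens);
keywords and slang match whole tokens, phrases match contiguous token
sequences (so a phrase split across a line break still matches), and emoji
are matched as codepoint subsequences on the raw text *before* tokenization,
because tokenizers mangle emoji. Every match occurrence is reported with its
pattern class; no distinction is attempted between intent, jokes, or
hyperbole. The bundled lexicon is a small non-clinical demonstration list —
validated clinical lexicons are external instruments and load from YAML/JSON
via `lexicon_from_file()`.

**Sentiment.** The scorer is a pluggable contract (text → label in
{negative, neutral, positive} plus scores summing to 1), so transformer
scorers can be adapted in. The bundled default is a transparent rule scorer:
valence-marked tokens from bundled wordlists, a negator ("not", "never",
"no") within the two preceding tokens flips a token's valence, majority vote
decides, ties and zero hits are neutral. It is deterministic, which is what
makes the test suite exact. A scorer failure on an entry degrades that entry
to neutral with a warning — a stream is never aborted mid-pipeline.

**Self-reference.** A closed first-person-singular token list (`i`, `me`,
`my`, `mine`, `myself`, `i'm`, `i've`, `i'd`, `i'll`, `im`). A POS tagger
would be the heavier alternative; the closed list is transparent and was
chosen deliberately — note `ill` is excluded because it collides with the
adjective. Negative self-reference is defined as (negative sentiment) AND
(self-reference), so it is a subset of negative entries by construction.

**Topics.** Ten supervised topics, each a seed-word set. The default
embedder is a term-frequency vector over the union seed vocabulary with
cosine similarity against each topic's uniform seed centroid; an entry is
assigned to the argmax topic if similarity reaches the threshold (default
0.2, a convention, not an estimate), else `OUTLIER`. Ties break
deterministically by topic order. Tokens outside the seed vocabulary do not
affect similarity — diffuse topics with overlapping vocabularies are exactly
the hard case, so seed-set overlaps are reported at load. A dense-embedding
adapter can replace the bag-of-words embedder; it is outside the tested
surface. The default ten topic names (treatment, family, sleep, sex, school,
death, substance use, eating, friends, plus a placeholder "future") and
their seed lists are demonstration placeholders.

## The synthetic generator

`synthetic_config()` + `generate_participant()` produce a participant record
*and* its ground truth. What it emulates, and the defaults chosen:

- **Study shape**: 180 days with the hospitalization on day 150, mirroring a
  6-month observation window with an admission late in it.
- **Entry volume**: daily counts from a zero-truncated negative-binomial law
  (mean 120/day, dispersion 10). Observed per-case volumes in this setting
  range from tens to hundreds of entries per day with clear
  over-dispersion; a Poisson law would under-disperse. No published
  distributional form exists for this process — the count law is a stand-in,
  not an estimate. Non-missing days are guaranteed one entry, so missingness
  is controlled solely by `missing_day_prob` (default 0.036, matching the
  ~96% keyboard-day coverage typical of this modality).
- **Base rates**: per-entry suicide-language probability 0.02 and negative
  sentiment 0.30 — negative sentiment is an order of magnitude more common
  than suicide language, which is what makes the ratio scales of the two
  metrics so different. Half of negative entries are self-referential.
- **Acute elevation**: a *step* multiplier over the onset window
  `[hospitalization_day - onset, hospitalization_day]` (defaults: suicide
  5× over the final days, negative sentiment 2×). A step is the simplest
  ground truth whose recovery is checkable in closed form
  (`expected_window_ratio()` gives the exact expected $R_w$ from the mixing
  proportions); ramp generators would be a natural extension.
- **Diurnal structure**: a four-bin weight vector (timestamps uniform within
  bin), because the analysis stratifies by exactly those four bins; plus an
  optional weekend multiplier on the suicide-language rate.
- **Text**: assembled from labeled template pools (30 neutral, 23 negative of
  which 8 self-referential, 16 suicide-flagged spanning all four pattern
  classes, 8 per topic). The pools are engineered to be unambiguous under
  the default labelers — only negative templates contain valence tokens,
  only self-reference variants contain first-person pronouns, only suicide
  templates contain lexicon patterns, and topic templates draw content words
  only from their own seed set. That is what makes label-recovery closure
  *exact*: running the default labelers on generated text reproduces the
  ground-truth labels with zero mismatches.

What the generator deliberately does **not** model: realistic adolescent
language (no context across entries, no ambiguity, no misspellings beyond
what the lexicon's slang covers), incoming messages (the sensing captures
only what the participant types), keystroke dynamics, and any correlation
between signals beyond the configured rates. Passing tests therefore
demonstrate that the *measurement chain* is correct and calibrated — not
that the labelers would perform well on real text, where transformer
sentiment models and validated lexicons face ambiguity the templates exclude
by design.

## Correspondence with clinician timelines

Clinician-coded risk events are day-level `(participant, date, category,
note)` rows over a 17-category controlled vocabulary; multi-day events are
repeated days. The published comparisons of NLP signals with such timelines
are visual; `correspondence()` is this package's quantitative
operationalization, and its matching rule is fully parameterized and
reported with results: a day is an *elevation day* when its daily proportion
reaches `threshold_multiplier` (default 2) times the study mean with at
least `min_entries` entries (default 5 — the guard keeps single-entry days
from registering spurious 1.0 proportions); an event-day *matches* when an
elevation day lies within `tolerance_days` (default 1). Both directions are
reported: the recall-like fraction of event-days matched and the
precision-like fraction of elevation days with a nearby event. Fractions are
monotone in tolerance (nondecreasing) and in the threshold (nonincreasing),
which the tests verify.

## Numerical and degenerate-input choices

- Zero study-wide flags make a ratio curve undefined: it is returned as `NA`
  with a warning, not an error, because one dead metric should not kill a
  multi-metric report.
- Windows with zero entries yield `NA` ratios; days with zero entries yield
  `NA` proportions.
- Exact similarity ties in topic assignment break by spec order; permuting
  the order only changes assignments on exact ties.
- Segmentation opens a new entry strictly when the inter-event gap *exceeds*
  the pause threshold (a gap of exactly 60 s with threshold 60 does not
  split); the threshold default of 60 s is a documented stand-in for an
  upstream value that is not public.
- Loess is fit with `surface = "direct"` so fitted values are exact rather
  than interpolated, keeping the group curve reproducible to the digit.
- All randomness flows from per-participant integer seeds; identical configs
  are byte-identical, which the end-to-end determinism test checks at the
  file-checksum level.

## Problem sizes used in validation

The shipped validation uses sizes chosen to make sampling error small
relative to the effects being recovered while staying desk-scale: null
calibration of $R_{10}$ over 200 homogeneous participants (90 days ×
100 entries/day; the fraction above 1 must sit in a band around ½ and the
mean within 3 SE of 1); elevation recovery over 100 participants with a 5×
step over the final five days (mean $R_5$ against the closed form; the
smoothed curve must peak at $w \le 5$); weekend-multiplier recovery over 50
participants; exhaustive-oracle equivalence on 500-entry text and
1,000-event segmentation fixtures; and exact label-recovery closure on a
~10,000-entry stream.

## Worked example

```{r, eval = FALSE}
library(acutelang)

cfg <- synthetic_config(participant_id = "demo", rng_seed = 7)
g <- generate_participant(cfg)

labels <- label_entries(g$record)
series <- daily_metrics(g$record, labels)

study_mean(series, "suicide")          # pooled whole-study frequency
curve <- window_ratio_curve(series, "suicide")
curve$ratio[5]                         # ~5x elevation at the 5-day window

split_periods(series, A = 10)          # acute vs baseline views
weekday_weekend_metrics(series)        # weekend/weekday pooled frequencies
render_case_panel(series, "suicide")   # centered panel with Day-0 marker
```

## Known limitations

- The bundled lexicon, valence lists and topic seeds are demonstration
  vocabularies; every scientific use requires study-specific instruments
  loaded from config.
- Single-label topic assignment (argmax): entries mixing topics get the
  dominant one. Multi-label assignment is a noted extension.
- No formal inference: the package quantifies within-person descriptive
  elevations; cross-participant statistical modeling is out of scope.
- The transformer sentiment adapter and dense topic embedders are contract
  slots only; their behavior is not covered by the deterministic test suite.
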