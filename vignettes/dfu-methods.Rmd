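---
title: "Measuring opinion polarization as distance from unimodality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring opinion polarization as distance from unimodality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfu)
```

## The model

An item rated by many people on an ordinal scale — negative/neutral/
positive sentiment, four levels of toxicity, K bins of a binned
continuous score — yields a histogram of relative frequencies
$f = (f_1, \dots, f_K)$. We call the opinions *polarized* when the
histogram splits into two or more opposing clusters, and *unpolarized*
when it has a single coherent mode, however wide. Dispersion measures
conflate the two: a flat-but-unimodal histogram is dispersed yet not
polarized, while a tight 60/40 split across adjacent extremes is
polarized with modest variance.

The distance from unimodality operationalizes this directly. A discrete
histogram is unimodal when some position $m$ exists with $f_{i-1} \le
f_i$ for $i < m$ and $f_{i+1} \le f_i$ for $i > m$; the uniform
histogram satisfies this trivially. Taking $m$ as the argmax of $f$, the
difference values

$$
d_i = \begin{cases}
f_i - f_{i-1} & i > m\\
f_i - f_{i+1} & i < m\\
0 & i = m
\end{cases}
\qquad \mathrm{DFU} = \max_i d_i
$$

are all non-positive exactly in the unimodal case, so $\mathrm{DFU} = 0$
iff the histogram is unimodal, and otherwise DFU is the largest
adjacent-bin rise where the frequencies ought to fall — the height of
the steepest valley wall, bounded by $\max f \le 1$. `is_unimodal()`
implements the definition by brute force over all candidate modes and
serves as an independent oracle; the test suite verifies
$\mathrm{DFU}=0 \iff$ unimodal exhaustively for every histogram with
$K \le 8$ on a 0.05 frequency grid.

```{r}
dfu(c(0.1, 0.2, 0.4, 0.2, 0.1))  # unimodal
dfu(rep(0.25, 4))                # uniform: unimodal by convention
dfu(c(0.5, 0, 0.5))              # the two-extreme split
```

### Numerical choices

* **Index ranges.** The difference values are defined at every position
  other than the mode, endpoints included. Excluding the endpoint bins
  would make a spike in the first or last category invisible and would
  contradict the monotonicity rule the statistic is built from.
* **Tied maxima.** The definition leaves the argmax ambiguous under
  ties. We evaluate the deviation at every tied position and report the
  minimum — the reading most charitable toward unimodality. It
  guarantees plateau-topped unimodal histograms score exactly 0 and
  makes the score independent of any left/right argmax convention; a
  property test confirms the reported value never exceeds the
  leftmost-argmax value.
* **Floor at zero.** $d_m = 0$ is always among the $d_i$, so DFU is
  non-negative analytically; the implementation still clamps at zero to
  guard against floating-point residue.
* **Zero bins** are legal frequencies and participate in the
  differences; no smoothing is applied.
* **Unnormalized input.** `histogram()` enforces the sum-to-1 invariant
  (tolerance 1e-9), but `dfu()` and `is_unimodal()` accept any
  non-negative mass vector as given — the difference rule applies to raw
  counts too, scoring on the count scale.
* **Tolerances.** Score comparisons in the tests are exact or at 1e-12;
  a sharper tolerance would only test the arithmetic of `max()`.

One property that might look plausible is false: moving mass from a
mode-adjacent bin onto the mode can *increase* DFU when the drained bin
falls below its outward neighbour (from $(0.3, 0.35, 0.3, 0.05)$, moving
all of bin 3 onto the mode opens a fresh valley and lifts DFU from 0 to
0.05). The tests assert the monotonicity only in the regime where it is
a theorem — the transfer capped so the drained bin stays at or above the
next bin outward.

## Baseline measures

Four conventional scores are provided for comparison, all on the
positions $1, \dots, K$ weighted by $f$:

* population standard deviation (`stdev_dispersion()`);
* Leik's ordinal consensus $D = 2\sum_i d_i/(K-1)$ with
  $d_i = F_i$ if $F_i < 0.5$, else $1 - F_i$, where $F_i$ is the
  cumulative relative frequency — here $m$ in the classical formula is
  the category count $K$, not a mode;
* the $d^2$ dispersion index $\sum_{i=1}^{K-1}(F_i - 0.5)$, implemented
  literally even though the literal form is sign-antisymmetric under
  scale reversal (it likely lost an absolute value in transmission); a
  `folded = TRUE` variant sums $|F_i - 0.5|$ and is reversal-symmetric,
  but is never used by default;
* kurtosis peakedness, the fourth standardized moment in the Pearson
  convention (normal = 3); `excess = TRUE` subtracts 3. Only the
  association with gold matters downstream, so the convention choice is
  cosmetic, but it must be stated to be reproducible. Zero-variance
  (single-category) histograms are rejected rather than given a
  sentinel value.

## Simulation design

`mixture_histogram()` draws $n$ points from a seeded Gaussian mixture
and bins them into $K$ equal-width, right-open bins (last bin closed)
spanning the sample range — the common histogram semantics; a fixed
`range` can be supplied when cross-sample comparability matters more
than covering every draw. Three presets are shipped: `unimodal` (unit
normal), `bimodal` (standard deviations 3 and 10, means ±12, equal
weights) and `trimodal` (standard deviations 5, 5, 10 at −25, 0, +30,
equal weights). The component means and weights of the multimodal
presets are this package's own choices, made once so that 10-bin
histograms of 10,000 draws are clearly multimodal; the scientific claim
attached to the presets is qualitative — the unimodal preset rounds to
DFU 0.00 in at least 49 of 50 seeds, the multimodal presets score
strictly positive — not any particular score value.

At 10,000 draws the unimodal case occasionally shows a one-count jitter
valley, which is why the claim is "rounds to 0.00 across seeds" rather
than exact zero; that matches how a practitioner reports simulated DFU
to two decimals.

## Annotation aggregation and the country-diversity resampling

`aggregate_annotations()` turns per-judgment records into per-item
histograms on a configurable scale (default: not toxic < hard to say <
toxic < very toxic; "hard to say" sits in the middle as a hedged
judgment, and the scale is configuration, not code). Raters without
country metadata are excluded from the distinct-country count.

`country_diversity_resampling()` asks whether polarized items attract
raters from more countries: split items at the q-th DFU quantile (items
exactly at the quantile go low), repeatedly sample `sample_size` items
per side without replacement, and count the repetitions in which the
high-DFU sample's mean distinct-country count strictly exceeds the
low side's. A one-sided sign-test p-value over repetitions supports the
count. Repetitions re-sample from the same finite corpus, so they are
not independent: when `sample_size` approaches a side's size the
repetition outcomes become strongly correlated and the success count
under a null corpus is no longer binomial-tight around 50%. The study
conditions used in the tests keep the per-side sample well below the
smaller side (400 of ~1,000 for the effect corpus of 4,000 items, 200 of
~1,500 for the null corpus of 6,000 items, 100 repetitions), where the
planted effect yields 100/100 successes and the null stays inside a wide
[20, 80] band.

`generate_synthetic_annotations()` plants the ground truth: a
`polarized_fraction` share of items gets labels split with random
imbalance between the two extreme categories (forcing a bimodal
histogram, DFU equal to the smaller extreme share), the rest get a
majority label with at most a minority of adjacent dissent on one side
(forcing DFU = 0); with `country_effect` on, polarized items draw rater
countries from a 10-country pool against 3 for the rest, and with it
off everyone shares one 5-country pool. This emulates the *structure* of
a crowd-annotated toxicity corpus — it does not emulate real label
noise, rater-specific bias, item difficulty, or any real country
distribution, so passing tests show the machinery detects a planted
effect and stays calibrated under a planted null, not that any real
corpus behaves this way.

## Sentiment time series

`discretize_sentiment()` maps a continuous valence score in [0, 1] to
negative (< 0.43), positive (> 0.61) or neutral (otherwise) — strict
inequalities, boundary scores neutral; the defaults are the customary
operating points for transformer-scored tweet valence and are plain
arguments. `cluster_polarization()` builds the 3-bin histogram per
(date, region) cluster and flags *peaks*, clusters with DFU strictly
above 0 (an optional threshold loosens this for noisy data). Dates are
kept as strings; no timezone arithmetic is attempted.

## Evaluation against gold judgments

`correlate_with_gold()` matches measure scores to gold
perceived-polarization judgments (a [0, 100] axis treated as an opaque
monotone score — rank and linear correlation need nothing more) and
computes Spearman (average ranks for ties, which K-bin histograms
produce often) or Pearson coefficients; anti-correlated baselines
legitimately report negative values. The shipped
`synthetic_gold_set()` fixture is a hand-constructed stand-in: 15
five-bin histograms whose gold values are a strictly increasing function
of the planted DFU, mixing wide-unimodal with narrow-bimodal shapes so
that dispersion cannot track gold perfectly. On it DFU attains Spearman
1 by construction; the meaningful check is relative — DFU exceeds every
baseline's absolute Spearman — and says nothing about correlations on
any real expert survey, which requires externally supplied data in the
`read_gold_csv()` format (`histogram_id, f1..fK, gold`).

```{r}
measure_comparison(synthetic_gold_set())
```

## Problem sizes and limitations

The test suite runs the exhaustive oracle-equivalence grid at $K \le 8$
(888,030 histograms at $K = 8$), 50 seeds of 10,000-draw simulations,
and resampling corpora of 4,000–6,000 items with 6 raters each — sizes
chosen so the full suite completes in well under a minute on one CPU
while leaving the statistical bands wide relative to their Monte Carlo
error.

Known limitations: DFU is defined for discrete ordinal histograms only
(continuous unimodality testing is a different problem with its own
tools); it is insensitive to the *distance* between opposing clusters by
design; very small rater counts make DFU coarse (with $n$ raters it is a
multiple of $1/n$); and the resampling analysis is descriptive — it
detects a mean difference under a planted design but does not model the
rater-to-country assignment process.
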