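---
title: "Aggregating expert intervals: methods behind intagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating expert intervals: methods behind intagree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intagree)
```

## The problem

Natural-resource managers routinely have to judge, with sparse data, how
likely each of many risk factors (salinity, drought, predation, fire, ...)
is to cause a management target to fail for each biological element under
their care (a waterbird assemblage, a woodland type, ...). Structured
expert elicitation fills the data gap: a panel of experts — ten in the
workflow this package supports — each state, for every risk-factor ×
element combination, an interval of likelihoods on \[0, 1\] (their lowest
and highest plausible values, drawn as the ends of an ellipse on the
questionnaire), a best estimate inside it, and their confidence (50–100%)
that the truth lies within the interval.

`intagree` turns those records into defensible group judgements in four
steps: interval standardization, expert calibration, interval-agreement
aggregation, and risk-matrix screening and ranking.

## Derived confidence intervals

Experts state intervals at different confidences, so raw intervals are not
comparable. `derive_ci()` rescales each side of the interval about the best
estimate $b$ by the factor $t/c$, where $c$ is the stated confidence and
$t$ the common target level (0.80 by default, configurable because any
level can be appropriate to a study):

$$\ell' = b - (b - \ell)\,\frac{t}{c}, \qquad
  u' = b + (u - b)\,\frac{t}{c}.$$

This is the only reading of "linear extrapolation" that uses all three
elicited points: an expert who stated exactly $t$ keeps their interval, a
more confident expert's interval is widened, a less confident one's
narrowed, and the best estimate is always retained. Because the likelihood
scale is physically bounded, extrapolations past \[0, 1\] are clipped after
scaling; the `clipped` flag records each such event (whether the original
study clipped or truncated is not documented, so clipping is this package's
explicit choice). A zero-width response derives to a zero-width interval.

## Calibration

Experts answer a set of known-answer questions with the same protocol.
`question_score()` computes, per question, the proportion of the expert's
*derived* interval that overlaps the pre-determined correct-answer
interval, $|ci \cap truth| / |ci|$, and `calibrate_panel()` averages each
expert's proportions into a calibration weight in \[0, 1\]. Weights are
absolute — a perfectly calibrated expert weighs 1 — and are deliberately
not re-normalized across the panel.

Two degenerate cases are scored by closed-set membership: a zero-width
expert interval scores 1 exactly when its point lies in the truth interval,
and a point-valued truth scores 1 exactly when it lies in the expert's
interval.

### A property of the scoring rule worth knowing

Dividing by the *expert's* width rewards narrow intervals that land inside
the truth interval. For an unbiased expert whose best estimate errs with
standard deviation $\sigma$, the expected score against a truth interval of
positive width is proportional to $(2\Phi(w/2\sigma) - 1)/w$, which is
decreasing in the interval width $w$: against interval-valued truths,
narrower (more overconfident) intervals score *better* in expectation. The
rule penalizes overconfidence only where it degenerates to hit-or-miss
membership, i.e. against point-valued truths. We keep the rule as defined
rather than "correcting" it, document the behaviour here, and use
point-valued truths in the test that checks overconfident panels earn lower
weights than honest ones. Practitioners composing their own truth sets
should prefer narrow or point-valued correct answers if they want
calibration to discipline overconfidence.

## Interval agreement aggregation

`aggregate_intervals()` sums the (weighted) indicator functions of the
experts' closed intervals. The resulting agreement function $a(x)$ equals,
at every likelihood $x$, the weighted number of experts whose interval
contains $x$: with ten unit-weight experts in complete agreement the
maximum is exactly 10. Three variants of a panel's records can be
aggregated (`aggregate_variant()`): `raw` intervals as elicited, `ci`
derived intervals, and `calibrated` derived intervals with each expert's
indicator scaled by their calibration weight — weighting the *height* of
the contribution, never the interval's width. Comparing the three shows
what standardization and calibration change.

### Numerical choices

* The representation is exact: breakpoints are the union of all interval
  endpoints; each open piece between consecutive breakpoints carries a
  constant level and each breakpoint its own point level. No grid is
  involved; grids appear only in test oracles and plotting.
* Intervals are closed on both ends, so levels at shared endpoints sum.
  This makes the min-max/max-max extraction well defined with no
  measure-zero surprises; endpoint openness in the original implementation
  is undocumented, so the closed convention is this package's documented
  choice.
* Because intervals are closed, the point level at a piece's left endpoint
  is always at least the piece level, so the global maximum is attained at
  a breakpoint; plateau detection uses a relative tolerance of $10^{-9}$ on
  levels to absorb floating-point noise in summed weights.
* Area is conserved exactly: $\int_0^1 a = \sum_e w_e\,(u_e - \ell_e)$,
  which the test suite asserts to $10^{-12}$.

## Crisp summaries

From the agreement function, `summarize_agreement()` extracts

* **min-max** — the smallest likelihood attaining the global maximum level
  of agreement (the start of the highest plateau); the default headline
  statistic because it is the most conservative,
* **max-max** — the largest such likelihood,
* **centroid** — the centre of gravity of the area under the curve,
  computed exactly piecewise,

plus the peak agreement level, the support, and the panel size. A maximum
attained only at an isolated breakpoint (possible with zero-width
responses) yields min-max = max-max = that point. The headline statistic is
configurable since other settings may prefer the centroid or max-max.

## The risk matrix

`risk_matrix()` enumerates every risk-factor × element combination (23 × 14
= 322 in the reference design). `apply_screening()` books the panel's
preliminary group judgement that some combinations carry at most a 5%
chance of causing target failure; screening is an input, not a computation.
`run_analysis()` aggregates each retained combination, and a combination
counts as *affected* when its headline likelihood strictly exceeds the
threshold (default 0.05, matching the screening level so screened-out
combinations and sub-threshold results are treated alike).
`rank_factors()` orders factors by affected-element count, breaking ties by
the factor's maximum headline likelihood and then alphabetically — the
tie-break is this package's convention, documented because the workflow
itself does not define one.

A note on the reference design's bookkeeping: 53 combinations remain for
detailed assessment out of 322, so 269 are screened out; a removed count of
297 sometimes quoted alongside these totals is arithmetically inconsistent
with them (297 + 53 = 350), and the package's invariant — retained plus
screened always equals the full cross-product — follows the consistent
reading.

## The synthetic panel generator

`generate_panel()` emulates the elicitation protocol so every stage is
testable without workshop data: each synthetic expert's best estimate is
drawn from a normal distribution centred at `true_value + bias` with
standard deviation `spread`, truncated to \[0, 1\] by clipping; the stated
confidence is uniform on \[0.5, 1\]; and the reported interval is the
central interval of the expert's belief at a coverage set by the behaviour
— equal to the stated confidence for `honest` experts, much lower
(`0.5 + 0.3(c - 0.5)`) for `overconfident`, higher (`c + 0.7(1 - c)`) for
`underconfident` — with half-width $\Phi^{-1}((1+\text{coverage})/2)\,
\sigma$. `generate_truth_set()` goes further and *constructs* responses
whose derived-interval overlap proportions equal prescribed values exactly
(stated confidence equals the target level, so derivation is the identity),
giving a closed-form oracle for weight recovery.

These are fixture conventions, not psychometric claims: real experts are
not exchangeable Gaussians, their errors correlate, and real confidence
statements cluster on round numbers. Passing tests on these panels
demonstrates the *arithmetic* of the pipeline — not that the method
elicits truth from real panels.

All generator draws flow from a single integer seed; the test suite uses
panels of 10 experts, truth sets of 4–6 questions, and Monte-Carlo loops of
30–200 seeds, sizes chosen to mirror the reference workshop while keeping
the default suite quick to run.

## Known limitations

* Only the basic type-1 interval agreement construction is implemented;
  higher-order (zSlice/type-2) generalizations are out of scope, as are
  alternative defuzzification schemes beyond min-max, max-max and centroid.
* The screening step and the truth-interval widths are user judgements;
  the package validates and bookkeeps them but cannot audit them.
* The calibration scoring rule's preference for narrow intervals against
  wide truth intervals (above) is inherent to the rule, not a bug, and
  should inform truth-set design.
* Interactions among risk factors are not modelled; each combination is
  aggregated independently.
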