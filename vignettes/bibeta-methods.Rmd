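---
title: "The BI-β scoring model: method, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The BI-β scoring model: method, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bibeta)
```

## The decision problem

A multicriteria decision problem supplies a decision matrix
$X \in \mathbb{R}_{\ge 0}^{n \times m}$ — $n$ alternatives scored on $m$
criteria — together with, per criterion $j$, an optimality direction, an
ideal value $l_j$ and a weight $w_j$ with $\sum_j w_j = 1$. The BI-β index
turns this into a 0–100 score per alternative in six stages:

1. **Decision matrix.** Values must be finite and non-negative.
   Internally alternatives are rows; tables arriving transposed
   (criteria in rows) are accepted through the reader's `orientation`
   flag and transposed once on entry, so every later stage works in one
   canonical layout and silent transposition bugs are impossible.
2. **Difference matrix.** $F_{ij} = |x_{ij} - l_j|$, the absolute
   deviation from the ideal. Ideals are either *supplied* (a reference
   value from the literature) or resolved as the *column mean*
   $\bar{x}_j$; the two policies may be mixed across criteria.
3. **Matching matrix.** With $y_j^- = \max_i F_{ij}$ the worst observed
   deviation per criterion, $M_{ij} = y_j^- - F_{ij}$: deviations are
   reflected so that *larger is better*, the alternative closest to the
   ideal attains the column maximum and the farthest drops to zero.
4. **Logarithmic transformation.** $Q_{ij} = \ln(M_{ij} + 1)$. The $+1$
   shift pins zeros at zero and keeps everything finite; the natural log
   (base fixed to $e$, no option) compresses large matched values so a
   single wide-range criterion cannot dominate. The transform is strictly
   increasing, so within-criterion orderings are preserved.
5. **Weighting and index reference values.** $A_{ij} = w_j Q_{ij}$;
   $R_j = \max_i A_{ij}$ is each criterion's best attainable
   contribution.
6. **Scores.** The in-class score $t_{ci} = \sum_j A_{ij}$ is normalised
   by the index reference score $b_{ri} = \sum_j R_j$:
   $$\mathrm{BI\text{-}\beta}_i = 100 \, \frac{t_{ci}}{b_{ri}} \in [0, 100].$$
   An alternative attaining every column maximum scores exactly 100; one
   at the worst observed deviation on every criterion scores exactly 0.
   Ranks use descending-score competition ranking.

Because the score is a ratio of sums of a per-column rescaling, it is
invariant to permuting criteria (with their specifications), equivariant
to permuting alternatives, and — with ideals held fixed — unaffected by
duplicating an alternative (a duplicate changes no column maximum and no
deviation). Under the column-mean ideal policy a duplicated row *does*
shift the resolved ideal, so that invariance is stated, and tested, for
supplied ideals.

## Design choices where the method description is open

**Matching-matrix mode.** The method's narrative for stage 3
distinguishes max- from min-direction criteria (max columns "preserved",
min columns reflected), while its single displayed formula reflects every
column. The two disagree only on max-direction columns. The package's
default, `mode = "uniform"`, applies the reflection to all criteria: the
deviation $F$ is already direction-agnostic (being a distance from the
ideal), the reflection is what makes *smaller deviation better* regardless
of direction, and every criterion in the motivating country study is
max-direction, so uniform mode reproduces that study exactly.
`mode = "direction_split"` implements the literal narrative for
comparison. Criterion direction otherwise enters only through the choice
of ideal value; no separate sign flip is applied, since the absolute
deviation is sign-symmetric.

**Score direction.** One sentence of the method's stage-6 description
inverts the ratio ($b_{ri}/t_{ci}$); the displayed formula, the bound
$0 \le \text{score} \le 100$ and every published score table are
consistent only with $t_{ci}/b_{ri} \times 100$, which is what the
package implements.

**Ranking ties.** Scores equal to 12 decimal places share the minimum
(competition) rank; display order among ties is alphabetical. The
12-decimal comparison treats pure float noise as a tie while keeping any
genuine score difference distinct.

**Weights.** Weight vectors must sum to 1 within `1e-9`; out-of-sum
vectors are rejected unless normalization is requested explicitly
(`normalize = TRUE`, or `--normalize-weights` in the CLI), in which case
the rescaling is logged. Reported outputs round scores and $t_{ci}$ to
2 decimals and weights to 3; full precision is retained internally.

## The neutral weighting scheme

The Global Health Security Index (GHSI) weights its six categories
equally and splits each category's unit weight evenly over its
indicators: with category sizes 6, 6, 7, 7, 6, 5 an indicator receives
1/6, 1/6, 1/7, 1/7, 1/6 or 1/5. The package keeps these as exact
fractions — the printed 3-decimal roundings (0.167, 0.143, 0.200) sum to
6.008 across 37 indicators, whereas the exact fractions sum to exactly
6, which is the only reading consistent with the published "Sum 6.000"
row. `normalize_neutral_weights()` then divides by that total, giving
1/36 ≈ 0.028 for Prevent/Detect/Norms indicators, 1/42 ≈ 0.024 for
Respond/Health, and 1/30 ≈ 0.033 for Risk, summing to 1 within `1e-12`.
Whether the original country study used rounded or exact neutral weights
is not stated; both agree at every reported precision.

## The GHSI country study

`read_ghsi_csv()` ingests a wide CSV (one row per country-year, one
column per indicator, scores in [0, 100]) against a shipped declarative
code map of the 37 indicators; matching is case- and
whitespace-insensitive and unmapped columns are dropped with a warning
rather than guessed at. Countries missing any indicator for a year are
rejected, not imputed — the published study reports complete 195 × 37
matrices and states no imputation rule. ISO alpha-3 and region columns
are carried as metadata but never scored. `ghsi_criterion_spec()` fixes
the study's configuration: all criteria max-direction, column-mean
ideals, normalized neutral weights.

The full public per-indicator dataset is distributed by its publisher
and is not bundled here. What the package ships instead is the published
*results* table for the top 33 countries of 2021
(`ghsi_reference_scores()`), which supports a self-consistency check —
$100 \, t_{ci} / b_{ri}$ must reproduce each published score within the
rounding of the 2-decimal $t_{ci}$ (observed maximum discrepancy ≈ 0.19,
bound 0.5) — but not a re-derivation of the scores from indicator data.
Runs against the real CSV use exactly the same code path as the shipped
fixtures (`cmd_ghsi()`).

## Rank concordance

Two score-induced rankings are compared with Spearman's $r_s$ and
Kendall's $\tau$. The classical formulas
($r_s = 1 - 6\sum d_i^2/(n^3 - n)$;
$\tau_a = 2(p - q)/(n(n-1))$ with $p$ concordant and $q$ discordant
pairs) are exact only without ties, and real composite-index data tie
frequently, so the defaults are the tie-aware forms mainstream software
reports — the product-moment correlation of average ranks, and $\tau_b$
with the tie-corrected denominator — with the classical forms available
as variants (`"paper"`, `"tau_a"`). All variants coincide on tie-free
data.

P-values are two-sided against the null of no monotonic association. For
$n \le 8$ the package enumerates all $n!$ pairings and reports the exact
permutation tail $P(|T| \ge |t_{obs}|)$; beyond that it uses the
$t$-approximation $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ with $n-2$ degrees of
freedom for Spearman and the normal approximation with tie-adjusted
variance for $\tau$. The switchover at 8 keeps full enumeration (40,320
permutations) affordable while the approximations are already accurate.
Decisions default to $\alpha = 0.01$, two-tailed. A p-value below the
reporting precision is displayed as an inequality (`< 0.001`), never as
0. Constant rankings make the tie-corrected statistics undefined and are
signalled as errors rather than silently returned as 0.

## The synthetic generator

`simulate_decision_problem()` draws complete decision matrices of
independent uniform scores on [0, 100] — the range and completeness of
composite health-security indicator data — with mandatory seeds and full
reproducibility. It deliberately does *not* imitate the correlation
structure, skewness or clustering of real indicator panels, so passing
property tests demonstrates correctness of the scoring arithmetic, not
robustness to realistic dependence patterns.

Two ground-truth rows can be planted. The planted ideal row equals the
per-criterion mean of the free rows; the planted worst row sits at the
end of the value range farthest from each ideal, which dominates every
other deviation since all values lie inside the range. When a plant is
requested the generated specification carries the ideal vector as
supplied values (the means of the free rows) rather than the mean
policy: this pins the planted rows at the exact 100 and 0 extremes —
bit-exact, not merely within tolerance — because the worst row's own
extreme values then cannot shift the ideal it is measured against.
`simulate_paired_rankings()` provides ranking fixtures with tunable
monotone association (exact copies or reversals at ±1, a Gaussian noise
mixture in between) and tie injection by equalising consecutive order
statistics up to the requested fraction of items.

## Numerical notes

- `log1p()` computes $\ln(M + 1)$ accurately near zero.
- $t_{ci} \le b_{ri}$ holds mathematically but the two sums can
  accumulate in different orders; the final score is clamped to
  [0, 100] so the bound is exact rather than exact-up-to-one-ulp.
- A criterion constant across all alternatives yields $y_j^- = 0$, hence
  a zero column in $M$, $Q$ and $A$: it contributes nothing to any score
  and simply drops out. Only when *every* criterion is constant is
  $b_{ri} = 0$ and the problem reported as unscorable.
- Weight-sum tolerance is `1e-9` on input, `1e-12` after normalization;
  the pipeline-vs-oracle agreement in the test suite is checked at
  `1e-9`, invariances at `1e-12`.

## Problem sizes exercised by the tests

The property suite runs the pipeline at the country-study scale
(195 × 37) and across 20 seeded random shapes up to 200 × 37;
entry-by-entry oracle comparisons use instances up to 10 × 6 where a
naive loop recomputation is transparent. Concordance statistics are
verified exhaustively against brute force for every ranking up to
$n = 7$ and the exact permutation test is cross-checked against a
20,000-draw Monte-Carlo tail at $n = 8$. These sizes were chosen so the
whole suite stays quick while covering the regimes the method is used
in.

## Known limitations

- Without the external per-indicator dataset, country-level scores are
  validated by self-consistency of the published results table, not
  re-derived from raw indicators.
- The published concordance table for the country study was produced
  with commercial software whose exact tie-handling variant is unstated;
  the tie-corrected defaults here are the standard forms, and p-value
  machinery is documented above, but bit-exact replication of that
  table's p-values is not promised.
- `direction_split` mode with min-direction criteria changes the scale
  of preserved columns relative to reflected ones; it exists to mirror
  the literal stage narrative and should be used for comparison, not as
  the default analysis.
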