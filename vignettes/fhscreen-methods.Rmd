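---
title: "Methods: pooled ICERs, COMER weighting and aggregate DCEA for FH screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled ICERs, COMER weighting and aggregate DCEA for FH screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhscreen)
```

## The problem

Economic evaluations of familial hypercholesterolemia (FH) screening are
heterogeneous: different countries, currencies, price years, decision
models, outcome measures (QALYs, life-years gained, adverse events or
deaths averted) and willingness-to-pay thresholds. `fhscreen` works at
the level of *extracted study summaries* — one incremental cost and one
incremental effect per (study, outcome) pair — and provides two linked
analyses: a deterministic evidence synthesis within homogeneous groups,
and an aggregate distributional cost-effectiveness analysis (DCEA) of
what a screening programme does to the socioeconomic health gradient.

It does not refit the source studies' Markov or decision-tree models,
perform likelihood-based meta-analysis of ratios, or conduct
person-level DCEA; those are out of scope by design.

## Evidence synthesis

### Grouping and pooling

Records are pooled only within a (screening strategy, outcome measure)
group — comparing a cascade QALY study to a universal deaths-averted
study would be meaningless. The pooled ICER is the ratio of sums,
$\mathrm{ICER} = \sum_i c_i / \sum_i e_i$, not the mean of ratios: it
answers "what does the portfolio of programmes cost per unit of health",
and it is invariant to how a study is split into cohorts whose average
equals it. Multi-cohort studies are first averaged arithmetically
(`combine_cohorts()`). Cost-saving studies keep their negative costs in
the sums; dominance ("less cost, more health") is flagged instead of
reporting a negative ratio only when the *totals* have that sign
pattern.

All monetary inputs are expected in the reference currency-year, 2023
US dollars. `convert_to_reference()` applies user-supplied
(purchasing-power-parity style) multipliers from a
`conversion_table()`; factors are inputs, never fetched, because the
conversion service is external to the analysis.

### Study-specific thresholds

Per-study net monetary benefit is
$\mathrm{NHB}_i = \lambda_i e_i - c_i$ with $\lambda_i$ the study's own
willingness-to-pay threshold after conversion. The encoded evidence base
(`table3_studies()`) carries a subtlety: converted thresholds are not
published anywhere, so the fixture back-solves them from the published
net-benefit column, $\lambda_i = (\mathrm{NHB}_i + c_i)/e_i$, and flags
them `back_solved`. The back-solved values agree to roughly five
significant figures across the outcome groups of the same study (e.g.
~\$50,731 for the same UK study in its QALY, events-averted and
deaths-averted rows), which is strong internal validation: a parsing or
encoding error in any of those cells would break the agreement.

### COMER weights

The comparative-efficiency weighting rule implemented here is

$$\omega_i = \frac{\mathrm{NHB}_i^{-2}}{\sum_k \mathrm{NHB}_k^{-2}},$$

i.e. weight proportional to the inverse *squared* net benefit, sign
ignored. The published analyses this package reproduces do not print
the formula; we identified this rule as the one that reproduces every
printed weight column to at least three significant figures *and* every
printed group TNHB (including a universal-screening TNHB cell it
reproduces exactly), and adopted it as the default. It is falsifiable —
user-supplied weights can be passed to `synthesize()` — and has clean
invariances that the test suite asserts: weights sum to one, are
unchanged by a common positive rescaling of all net benefits, permute
with their inputs, and strictly decrease in $|\mathrm{NHB}|$. Two
printed weight cells in the deaths-averted groups disagree with the
full-precision rule by more than their own rounding (0.9633 vs 0.96226
recomputed); we treat these as printing slips because the TNHB cells of
the same groups, which depend on the full weight vector, *are*
reproduced.

A weight of this form diverges as $\mathrm{NHB}_i \to 0$, so
`comer_weights()` refuses exact zeros rather than silently returning a
degenerate one-hot vector.

### Uncertainty intervals

Two propagation modes:

* **paper** (default, for reproduction): every interval is the point
  estimate ±25%. The published synthesis intervals all have exactly this
  structure, and the acceptance tests verify it across all seven groups.
* **delta**: per-study cost and effect intervals (the ±50% default of
  `default_interval()` where the source reported none; reported
  intervals take precedence) are read as 95% normal intervals
  (SE = half-width / 1.96), pooled in quadrature, and propagated through
  the first-order ratio variance
  $\operatorname{var}(R) \approx R^2\left(\frac{\sigma_c^2}{c^2} +
  \frac{\sigma_e^2}{e^2} - \frac{2\rho\sigma_c\sigma_e}{ce}\right).$
  This is accurate when the denominator's coefficient of variation is
  small; the test suite checks it against a $10^6$-draw Monte-Carlo
  ratio interval at CV 0.05, where the endpoints agree within 1%. The
  TNHB interval stays proportional in both modes because no sampling
  model for the weights is defined.

## Aggregate DCEA

A scenario is (ΔQALY per person, Δcost per person, opportunity-cost
threshold $K$ per QALY, $N$ people screened, a subgroup distribution,
aversion $\varepsilon$). Steps:

1. **Population split** $n_j = N \cdot \mathrm{popshare}_j$, real-valued
   (no integer rounding), equal fifths by default — deprivation
   quintiles are population quintiles by construction.
2. **Group net health benefit**
   $\mathrm{NHB}_j = \Delta QALY \cdot n_j - N \cdot \Delta cost \cdot
   d_j / K$: the gain is spread per capita, the forgone health is spread
   by the opportunity-cost shares $d_j$. Summing over $j$ gives the
   closed form $N(\Delta QALY - \Delta cost/K)$ exactly, a conservation
   law the tests assert.
3. **Post-intervention health**
   $h_j \to h_j + \mathrm{NHB}_j / n_j$ (per-person increment on
   baseline quality-adjusted life expectancy). A scenario that drives
   any group's health to zero or below aborts with a clear error — the
   Atkinson index is undefined there, and such a scenario is outside the
   model's domain anyway.
4. **Inequality and EDEH**: Atkinson index over the five group values
   (unweighted mean, as the index is defined on equal-sized quintiles; a
   population-share-weighted variant is available via the `pop_share`
   argument for non-quintile groupings), then
   $\mathrm{EDEH} = N (1 - A(\varepsilon)) \bar h$.
5. **Equity impact** $= \Delta\mathrm{EDEH} - \Delta\mathrm{NHB}$,
   positive iff the programme reduces inequality.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| baseline QALE | 63.21 … 75.00, linear | years | published endpoints for the most/least deprived quintiles; the unpublished middle quintiles are linearly interpolated and overridable |
| opportunity-cost shares $d_j$ | 0.26 … 0.14, linear | proportion | published endpoints (26% borne by IMD1, 14% by IMD5); interpolation sums to 1 exactly |
| population shares | 0.2 each | proportion | quintiles |
| $\varepsilon$ | 10.95 | — | empirical UK estimate of health-inequality aversion; configurable |
| $K$ | per scenario | \$ (or study currency)/QALY | each scenario uses its own study's societal threshold |

At $\varepsilon = 10.95$ the social welfare function is extremely
inequality-averse: proportional gaps are raised to the power
$1-\varepsilon = -9.95$, so a few years of QALE difference produce an
index near 0.02 and small redistributions move EDEH by whole QALYs.
$\varepsilon = 1$ is handled by its analytic geometric-mean limit
$A = 1 - \mathrm{GM}(h)/\bar h$, and the implementation is continuous
there to below $10^{-6}$.

### What is and is not reproducible

The total-NHB column of the published DCEA table follows from its
printed inputs alone and is reproduced to ±1 QALY. The incremental-EDEH
column does **not**: it depends on the exact (unpublished) quintile
baselines, and the published per-person baseline EDEH of 69.72 years is
itself inconsistent with linear interpolation between the printed
endpoints (the interpolated vector gives 67.77). Under the interpolated
defaults, cost-increasing scenarios concentrate opportunity costs on the
most-deprived quintile and can show a *negative* equity impact where the
original supplementary-data analysis reported a positive one;
cost-saving scenarios reproduce the published direction. The tests
therefore assert EDEH/Atkinson behaviour through properties (bounds,
Pigou–Dalton transfers, $\varepsilon$-monotonicity, the $\varepsilon=1$
limit, a frozen high-precision regression constant) and an independent
step-by-step recomputation, not through the published EDEH cells. One
DCEA row (Crosland) is additionally flagged `known_discrepancy` because
its printed cells are partially garbled at the source.

## The synthetic-data generator

`generate_studies()` emulates the statistical structure of an extracted
evidence base: per-study effects lognormal
(`effect_scale` median, `effect_sdlog` spread), costs
`true_icer * effect * (1 + noise)` with Gaussian noise of CV
`cost_noise_cv`, optional flips to cost-saving with probability
`dominance_prob`, thresholds uniform over `wtp_range`, and ±50% default
intervals attached. Everything is seeded and reproducible.

Defaults: `cost_noise_cv = 0.2` (a moderate dispersion of costs around
the frontier) and `effect_sdlog = 0.2`. The effect spread deserves a
note: the pooled ICER's relative error is an effect-weighted mean of the
cost noise, with median about
$0.675\,\mathrm{cv}/\sqrt{n/e^{\sigma^2}}$, so the generator's own
consistency property (median error below 2% at 50 studies, CV 0.2)
pins $\sigma \lesssim 0.3$; 0.2 keeps the effective sample size close to
the nominal one. Real evidence bases with order-of-magnitude effect
spreads (population programmes vs single-family cascades) are emulated
by raising `effect_sdlog`, at the cost of slower pooled-ICER
convergence — which is a real feature of ratio-of-sums pooling, not an
artifact.

What the generator does *not* emulate: correlated cost-effect pairs
from a common decision model, heterogeneity of perspectives and time
horizons, and systematic between-country price differences. Passing
tests on synthetic data therefore demonstrate the estimators' internal
consistency, not robustness to those real-world features.

## Numerical choices

* COMER weights rescale by the smallest $|\mathrm{NHB}|$ before
  squaring, so magnitude ranges spanning hundreds of orders of magnitude
  neither underflow nor overflow.
* Study tables serialize numerics as 17-significant-digit decimals (CSV
  and JSON), making write/load round trips bit-exact.
* Group ordering (strategy, then outcome, in fixed enumeration order) is
  deterministic, and `run_all()` output is byte-identical across runs on
  identical inputs.
* Intervals are plain ordered pairs; negative points swap endpoints so
  `low <= high` always holds.
* Test problem sizes: the Monte-Carlo check of the delta interval uses
  $10^6$ draws; parameter recovery uses 100 seeds × 50 studies; the full
  suite runs in a few seconds on one core.

## Limitations

* The subgroup distribution is UK-specific (IMD quintiles); applying it
  to scenarios from other countries, as the aggregate approach must,
  assumes the gradient shape transfers.
* Deterministic pooling has no between-study variance: the ±25% and
  ±50% rules are conventions, not estimated uncertainty.
* The back-solved thresholds inherit the rounding of the published
  net-benefit cells (±1 USD).
* Aggregate (group-level) DCEA only; no person-level analysis, no
  welfare functions beyond Atkinson, no probabilistic DCEA.
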