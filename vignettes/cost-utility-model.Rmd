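---
title: "A lifetime cost-utility model for lateral versus posterior lumbar interbody fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime cost-utility model for lateral versus posterior lumbar interbody fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbarCUA)
```

## The decision problem

Single-level lumbar interbody fusion can be performed through a lateral,
minimally invasive approach (LLIF) or through the standard open posterior
approach (PLIF). The lateral approach spares the posterior musculature and
uses a larger interbody cage, but the implant is considerably more
expensive; the posterior approach is cheaper per operation but is
associated with more blood loss and, in the registry cohort this package
emulates, a better one-year utility score. Whether the lateral technique
is worth its price in a middle-income health system is therefore an
empirical question about *lifetime* costs and quality-adjusted life-years
(QALYs), not about the index admission alone.

`lumbarCUA` implements the full decision-analytic pipeline for that
question from a societal perspective: a short-term decision tree feeding a
five-state Markov cohort model run over a lifetime horizon, incremental
cost-effectiveness analysis against the Thai willingness-to-pay (WTP)
threshold, a one-way deterministic sensitivity analysis (tornado), and a
probabilistic sensitivity analysis (PSA) with cost-effectiveness plane,
acceptability curves and switch-point WTP. A synthetic patient-level
cohort generator stands in for the registry data so every estimation step
is testable.

## Model structure

**States.** `well`, `complications`, `index_revision` (reoperation at the
fused level), `adjacent_revision` (reoperation at a neighbouring level),
and absorbing `death`. The decision tree allocates the cohort across the
four alive states at cycle 0 according to short-term surgical outcome;
annual cycles then move patients between states.

**Transitions.** Annual disease transition probabilities are inputs per
strategy (well to either revision state, complications to index revision,
revision states back to well or to each other). Background mortality is
applied first in every cycle at the age-specific probability $q_a$, and
the disease transitions act on survivors, i.e. every printed probability
is scaled by $(1-q_a)$. This ordering guarantees a row-stochastic matrix
for any life table; the additive alternative can push row sums past 1 at
high ages and was rejected. Mortality is identical across strategies (no
excess perioperative or revision mortality is modelled — the sources
provide none).

**Accrual and discounting.** Cycle length is one year. State membership
is evaluated at the end of each cycle; the cycle-$t$ contribution is the
occupancy-weighted state cost and utility discounted by $(1+r)^{-t}$ with
$r = 3\%$ per year. Upfront surgical costs (interbody cage, posterior
instrumentation, optional BMP2, and an arm-specific residual index-surgery
cost covering ward, surgeon and anesthesia components not itemised in the
input table) enter undiscounted at $t=0$. A half-cycle correction is
available (`settings$half_cycle_correction`) but off by default; the
calibration below was performed under end-of-cycle accrual, and the
published totals are reproduced without it.

**Horizon.** Ages 62 (the cohort's mean age at surgery) to 100, with the
final cycle forcing extinction, i.e. 38 annual cycles.

**Economic outputs.** Increments are oriented PLIF minus LLIF — the
orientation under which both printed increments are positive — and the
ICER is their ratio. Net monetary benefit, $\mathrm{NMB} = \lambda E - C$,
gives the threshold decision rule; `preferred_strategy()` implements the
equivalent quadrant-aware ICER rule (in the southwest quadrant the
cheaper strategy is preferred when the ICER of moving to the costlier one
exceeds $\lambda$) and the test suite proves the two agree in all four
quadrants. The Thai threshold is 160,000 THB per QALY converted at
31.98 THB/USD, i.e. 5003 USD/QALY.

## Parameter distributions

Every input row carries a base-case mean and a low–high range interpreted
as a 95% interval, so $\mathrm{SE} = (\mathrm{high}-\mathrm{low})/(2
\times 1.96)$. Probabilities and utilities get beta distributions and
costs gamma distributions, fitted by the method of moments:

* beta: $k = m(1-m)/\mathrm{SE}^2 - 1$, shapes $(km, k(1-m))$;
* gamma: shape $= m^2/\mathrm{SE}^2$, rate $=$ shape$/m$.

Both fits reproduce the printed mean exactly, which the test suite checks
for every row. Utility ranges follow a mean $\pm 10\%$ rule with the
upper bound capped at 1.

Two printed rows are internally inconsistent (a base case outside its own
range: the LLIF index-revision-to-well probability 0.0979 with range
0.010–0.088, and the PLIF adjacent-revision utility 0.679 with range
0.680–0.747), and one utility range deviates from the $\pm 10\%$ rule
(PLIF well, 0.890–0.979 where the rule gives 0.801–0.979). The loader
never corrects these: they are loaded verbatim and surfaced in
`$warnings`, in every manifest, and as `flagged` columns downstream.

```{r}
p <- default_parameters()
p
```

## Calibrated inputs

Three model inputs are not pinned down by the published tables: the
decision-tree allocation, the background-mortality table, and the
arm-specific residual upfront cost. They are set by a committed
calibration (`analysis/01_calibrate.R`) against the published base case,
and are deliberately the *only* free inputs — utilities and transition
probabilities stay at their printed values.

* **Mortality** is Gompertz, $q(a) = \alpha e^{\beta (a-62)}$, with the
  slope fixed a priori at $\beta = 0.10$ (adult mortality doubling every
  ~7 years) and the level $\alpha$ calibrated. The result
  ($\alpha \approx 0.0052$; 76% of the cohort alive at 80, 42% at 90) is
  an optimistic but shaped-like-a-life-table survival curve: the
  published lifetime QALY totals, under 3% discounting and the printed
  utilities, imply close to 16 discounted person-years from age 62 and
  cannot be reached under markedly heavier mortality. The table ships as
  an editable CSV fixture (`mortality_calibrated.csv`), so users with a
  national life table can substitute their own and recalibrate.
* **Decision tree**: the PLIF cohort starts entirely `well`; the LLIF
  cohort starts with a calibrated 14.6% share in `complications`. This
  is the only workable allocation lever: seeding the adjacent-revision
  state would add so much annual cost that the LLIF residual would need
  to be negative, and index-revision seeding is transient (its exit rate
  is ~10%/year) with negligible lifetime effect. The complications share
  absorbs the gap between the printed one-year utilities and the printed
  lifetime QALY increment that transitions alone cannot produce.
* **Residual upfront costs** (4059 USD LLIF, 1523 USD PLIF) close the
  total-cost identity exactly and are reported in `calibration.json` and
  every run manifest.

The calibration minimises squared error on the printed PLIF lifetime
QALYs (13.63) and the printed incremental effectiveness (0.15), then
solves the residuals in closed form. The committed configuration
reproduces costs of 30,124 / 33,003 USD and QALYs of 13.48 / 13.63 to
printed precision, with a base-case ICER of 19,193 USD/QALY — within 1%
of the published 19,359, the difference being rounding in the printed
increments.

```{r}
bc <- run_base_case(p)
bc$cea
```

## One-way sensitivity analysis

`one_way_dsa()` moves each input row to its low and then its high bound.
The output metric is the incremental NMB at the threshold rather than the
ICER: the ICER is unstable when the incremental effect approaches zero at
a bound, while the NMB difference is linear and keeps its sign
interpretable; the per-bound ICERs are reported alongside. Rows flagged
as internally inconsistent participate with their printed bounds but are
excluded from the *driver ranking*: for such a row the excursion from a
base case lying outside its own printed range measures the
inconsistency, not parameter uncertainty (the flagged LLIF
index-revision-to-well row would otherwise rank second on spread). The
three leading drivers among consistent rows are the LLIF well utility,
the PLIF well utility, and the PLIF well-to-adjacent-revision
probability.

## Probabilistic sensitivity analysis

Each of 1000 simulations draws every moment-feasible parameter once and
runs both strategies on the same draw set. Three design choices matter
and are worth stating explicitly:

* **Flagged rows are sampled.** Both inconsistent rows still admit valid
  beta moment fits from their printed mean and range, so they vary in
  the PSA like every other row; holding them fixed would understate the
  uncertainty the printed table encodes. Only zero-width rows (two
  non-medical unit costs) are held at base case, and every exclusion is
  listed in `$held_fixed`.
* **Common random numbers with a provenance-based grouping.** One
  stratified uniform drives each *draw group*: the two strategies'
  utilities for the same health state share a draw (both arise from the
  same registry instrument at the same follow-up, so their errors are
  common, and what matters for the comparison is their printed gap);
  transition rows that repeat one printed source estimate within a
  strategy share a draw (a reused estimate is one random quantity, not
  four independent ones); cost rows shared between arms share a draw.
  Distinct literature sources vary independently across strategies.
  This concentrates the Monte Carlo variance on genuine between-arm
  evidence differences instead of inflating it with artificial
  independent noise; fully independent sampling roughly doubles the
  spread of the incremental effect and produces an acceptability curve
  inconsistent with the deterministic analysis.
* **Stratified draws.** Uniforms come from a seeded Latin hypercube
  (`lhs`), which stabilises the tail summaries (acceptability
  percentages, switch point) at n = 1000 without changing any marginal
  distribution; `method = "simple"` gives plain `runif` sampling.

About 69% of draws fall where LLIF is cheaper and less effective. On the
acceptability side there is a labelling subtlety worth documenting: with
increments oriented PLIF minus LLIF, the probability that the
*incremental* NMB is positive — equivalently that the per-draw ICER falls
below the threshold — is the quantity conventionally quoted for the
intervention under an ICER-versus-WTP acceptability rule, and it is what
`prob_incremental` in the `ceac()` output and the 13–15% figure at
5003 USD/QALY refer to. The strategy-wise curves (`prob_llif`,
`prob_plif`), which always sum to 1, show the complementary picture: the
cheaper LLIF has the higher NMB in the large majority of draws at the
Thai threshold, and the preferred strategy switches where the curves
cross, at roughly 19,600–21,500 USD/QALY depending on seed (n = 1000).
The switch estimator interpolates the 0.5 crossing on a 0–40,000 grid in
steps of 100, bisecting exact ties so that it converges to the median
per-draw indifference threshold.

## Synthetic cohort generator

`generate_cohort()` emulates the registry's two arms (59 LLIF, 77 PLIF)
at the level of individual patients. Bounded scores — EQ-5D-5L utilities
(floor −0.28, a conventional worst-health index; ceiling 1), ODI and
EQ-VAS (0–100) — are truncated normal with post-truncation moment
correction, so the *realised* mean and SD match the printed summaries
despite the truncation. Positive right-skewed measures (blood loss,
operative time, length of stay) are gamma. Degenerate SD-zero specs
produce point masses; means outside scale bounds are rejected.

What the generator reproduces: per-measure means and SDs, arm sizes, sex
mix, and hence the group-comparison table (pooled-variance t primary,
Welch alongside) and the utility-estimation step with its ±10% ranges.
What it does not reproduce: within-patient correlation between measures
(records are drawn independently per measure), longitudinal pre/post
coupling, and any clinical event process linking complications to
revisions — the state-level utilities for the rarely observed states are
direct mean inputs, not simulated outcomes. Passing tests on synthetic
data therefore validate the estimation arithmetic, not the clinical
realism of the joint distribution.

EQ-5D-5L profiles are scored additively against a pluggable value-set
table; the packaged `value_set_synthetic.csv` is a synthetic example with
plausible decrement magnitudes, not a national tariff, and exists so the
scoring path is exercisable end to end.

## Numerical choices and degenerate inputs

* Ranges are 95% intervals; a zero-width range is flagged degenerate and
  held fixed everywhere (spread 0 in the tornado, excluded from PSA).
* Under this reading no beta spec whose range lies in [0, 1] can be
  moment-infeasible (the implied SE never reaches the binomial bound);
  the infeasibility guard remains for programmatic specs.
* The engine's terminal cycle forces $q = 1$ so occupancy mass ends in
  `death` exactly; mass conservation is asserted at $10^{-9}$ per cycle.
* Ties: NMB ties prefer LLIF (the cheaper option) consistently in both
  decision rules; CEAC probabilities use a strict inequality, so a
  measure-zero tie set cannot double-count.
* The brute-force oracle (exhaustive path enumeration) bounds engine
  error at $10^{-9}$ for up to 5 cycles; the geometric-series closed
  form pins discounting.

## Problem sizes

The shipped analyses use the study's own scales: 38 annual cycles, 35
parameter rows, 1000 PSA simulations, and cohorts of 59 + 77 patients
(scaled 100-fold in recovery tests). The full test suite and all
analysis scripts run in well under a minute on a single core.

## Limitations

The three calibrated inputs are identified only jointly: other
(mortality, allocation, residual) triples could reproduce the same four
published totals, so the calibrated values should be read as one
consistent completion of the published model, not as estimates of Thai
mortality or complication incidence. The complications state is
reachable only from the decision tree (no printed transition feeds it),
so its occupancy is a t = 0 artefact. Memoryless states mean revision
history does not alter subsequent risk. And the acceptability-labelling
convention described above should be kept in mind when comparing the
strategy-wise curves with published intervention-labelled ones.
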