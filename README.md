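# lumbarCUA

Lifetime cost-utility analysis of lateral (LLIF) versus open posterior
(PLIF) single-level lumbar interbody fusion, from a societal perspective
in the Thai health system.

Minimally invasive lateral fusion spares the posterior musculature but
carries a much more expensive implant; open posterior fusion is cheaper
per operation with more blood loss and, in the registry cohort emulated
here, a better one-year utility. `lumbarCUA` turns that trade-off into a
tested decision model:

* a short-term **decision tree** allocating the surgical cohort by
  outcome into four alive states;
* a five-state annual-cycle **Markov cohort model** (well,
  complications, index revision, adjacent revision, death) with
  age-specific background mortality applied before disease transitions,
  a lifetime horizon (ages 62–100) and 3%/year discounting of costs and
  QALYs — the incremental cost-effectiveness ratio is
  `ICER = ΔC/ΔE` with increments oriented PLIF − LLIF, judged against a
  willingness-to-pay of `160,000 THB / 31.98 THB·USD⁻¹ = 5003` USD/QALY
  via net monetary benefit `NMB = λ·E − C`;
* **sensitivity analyses**: a one-way tornado on every input row
  (low/high bounds read as 95% intervals) and a 1000-draw probabilistic
  analysis with moment-matched beta (probabilities, utilities) and gamma
  (costs) distributions, CE plane, acceptability curves and switch-point
  WTP;
* a **synthetic patient-level cohort generator** reproducing the
  registry's printed group summaries (n = 59 vs 77; blood loss,
  operative time, stay, utilities, ODI, EQ-VAS) so the utility
  estimation and group comparisons are testable without patient data.

The methods vignette (`vignettes/cost-utility-model.Rmd`) documents the
model, the three calibrated inputs (background mortality level, LLIF
short-term complication share, residual upfront costs) and every
numerical convention.

## Worked example

```r
library(lumbarCUA)
p <- default_parameters()      # packaged input table + calibration
L <- run_strategy(p, "LLIF")
P <- run_strategy(p, "PLIF")
compute_icer(L$cost, L$qaly, P$cost, P$qaly)
```

```
<cea_result>  (increments: PLIF minus LLIF)
 strategy  cost  qaly
     LLIF 30124 13.48
     PLIF 33003 13.63
  d_cost 2879 USD, d_qaly 0.1500 QALY, ICER 19193 USD/QALY
  LLIF in SW quadrant; NMB-preferred at WTP 5,003: LLIF
```

Read: over a lifetime the lateral technique costs 2,879 USD less and
yields 0.15 fewer QALYs per patient than the posterior technique; moving
from LLIF to PLIF buys a QALY at ~19,193 USD, far above the 5003 USD
threshold, so the extra effectiveness of PLIF is not affordable — and
conversely, under the ICER-versus-threshold acceptability convention the
costlier comparison is rejected. The probabilistic analysis:

```r
psa <- run_psa(p, n_sims = 1000, seed = 1)
100 * prob_cost_effective(psa, 5003, "PLIF")  # 14.8 (% of draws, seed 1)
switch_wtp(ceac(psa))                         # 19600 USD/QALY (seed 1)
```

About 69% of draws fall where LLIF is cheaper and less effective; the
acceptability of the incremental comparison at the Thai threshold is
13–15% across seeds, and the preferred strategy switches at roughly
20,000 USD/QALY. The tornado's three dominant drivers are the LLIF well
utility, the PLIF well utility and the PLIF well→adjacent-revision
probability (`analysis/03_one_way_dsa.R`).

## Analysis scripts

Numbered drivers under `analysis/` re-run the whole study and write
their tables beneath `results/`:

| script | what it does |
|---|---|
| `01_calibrate.R` | calibrates mortality level, decision-tree share and residual costs; commits `inst/extdata/mortality_calibrated.csv` + config fields |
| `02_base_case.R` | base-case totals, increments, ICER, cohort traces |
| `03_one_way_dsa.R` | tornado CSV and top drivers |
| `04_psa.R` | PSA draws, CEAC, switch WTP, CE-plane/CEAC figures |
| `05_synthetic_cohort.R` | synthetic cohort, group-comparison table, state utilities with ±10% ranges |

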