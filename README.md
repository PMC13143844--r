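# pvep

Pharmacovigilance signal detection for drug-induced eosinophilic pneumonia
(EP) from spontaneous adverse-event reports.

EP is a rare interstitial lung disease in which eosinophils accumulate in
the pulmonary parenchyma and airways; drugs are among its recognized
triggers, and most of the evidence is anecdotal. Spontaneous-report
databases (FAERS and similar) allow systematic screening: for each drug a
report-level 2×2 table is built — `a` case reports with the drug as primary
suspect, `b` non-case reports with it, `c` cases without it, `d` the rest —
and disproportionate reporting is quantified by

- **ROR** = ad/bc with `CI95 = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`,
- **PRR** = [a/(a+b)]/[c/(c+d)] with the Pearson χ²,
- **IC** = log₂(aN/[(a+b)(a+c)]) with a delta-method IC025,
- **EBGM** (observed/expected form) with a one-sided 95% EBGM05,

with a signal called positive when any method fires (PRR method:
n ≥ 3 ∧ PRR ≥ 2 ∧ χ² ≥ 4; ROR method: CI lower bound > 1; IC method:
IC025 > 0). Onset dynamics are modelled by a Weibull fit of
time-to-onset — shape β < 1 is an early-failure pattern (events cluster
soon after exposure), β > 1 wear-out — and risk factors are screened by a
univariate filter, LASSO with 10-fold cross-validation, and multivariable
logistic regression. The package is aimed at pharmacoepidemiologists and
safety scientists who want this workflow reproducible, tested, and
exercisable end-to-end on synthetic data with planted ground truth.

## Worked example

Simulate a reporting stream with two planted drugs — a daptomycin-like
antibacterial (odds multiplier 12, early onset) and a durvalumab-like
checkpoint inhibitor (multiplier 5, wear-out onset) — then run the full
pipeline:

```r
library(pvep)
cfg <- sim_config(
  50000,
  drugs = list(
    drug_spec("DAPTOMYCIN", 0.01, 12, tto_shape = 0.93, tto_scale = 25),
    drug_spec("DURVALUMAB", 0.01, 5,  tto_shape = 1.14, tto_scale = 80)
  ),
  background_event_rate = 0.01,
  missingness = list(age = 0.05, weight = 0.1, sex = 0.02,
                     event_date = 0.3, start_date = 0.3),
  duplicate_rate = 0.05, seed = 42
)
store <- dedup_reports(as_report_store(simulate_reports(cfg)))
cases <- extract_cases(store, smq_eosinophilic_pneumonia())
panel <- signal_panel(cases, store)
```

The planted rows of the panel:

```
       drug n_reports    ror ror_lcl ror_ucl    prr   chi2    ic ic025  ebgm
 DAPTOMYCIN        54 11.791   8.772  15.850 10.585 429.78 3.276 2.849 9.688
 DURVALUMAB        20  3.899   2.472   6.149  3.776  39.86 1.880 1.222 3.679
 ebgm05     p_adj positive
  7.563 8.009e-35     TRUE
  2.513 1.798e-05     TRUE
```

Both planted signals are recovered (ROR 11.8 and 3.9 against planted odds
multipliers 12 and 5; every method positive). Onset analysis and the
regression cascade:

```r
tto <- compute_tto(cases, store)
tto$audit
#> TTO exclusion audit: 577 cases, 311 excluded (53.9%: 304 missing dates,
#>   7 invalid), 266 retained
fit_tto_weibull(tto$records$tto_days[tto$records$drug == "DAPTOMYCIN"])
#> Weibull onset fit (n = 27): scale 16.82 days (95% CI 11.20-25.27),
#>   shape 0.98 (95% CI 0.74-1.30)
#> empirical median 9.0 days (IQR 5.5-17.5); early pattern

sc <- screen_candidates(panel, min_n = 4, p_adj_max = 0.01)
mm <- build_model_matrix(store, cases, sc$drug[sc$pass])
ls <- lasso_select(mm, seed = 7)
fit_logistic(mm, ls$selected)
#> multivariable logistic model: 2 terms
#>    variable   or or_lcl or_ucl    p_adj separation
#>  DAPTOMYCIN 13.9  10.11  19.06 4.64e-59      FALSE
#>  DURVALUMAB  4.4   2.68   7.22 9.14e-09      FALSE
```

The audit shows the date-completeness bookkeeping (53.9% of cases lack
usable dates under the 30% per-date missingness set above); the Weibull
shape near 1 with an empirical median of 9 days reflects the planted
early-onset distribution at a small fitted n; and the final logistic ORs
(13.9 and 4.4, CIs covering 12 and 5) recover the planted effects after
LASSO selection. `run_pipeline(run_config(cfg, seed = 1))` performs the
same sequence end-to-end and writes CSV artifacts plus a JSON manifest
with per-stage counts and checksums.

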