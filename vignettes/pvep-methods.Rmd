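---
title: "Methods: disproportionality, onset modelling and risk screening for drug-induced eosinophilic pneumonia"
author: "pvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, onset modelling and risk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`pvep` implements a complete spontaneous-report pharmacovigilance workflow
for drug-induced eosinophilic pneumonia (EP): ingestion of FAERS-dialect
quarterly ASCII tables, FDA-style deduplication, case retrieval through a
Standardized MedDRA Query (SMQ) term set, a four-metric disproportionality
panel with positivity rules and multiplicity control, Weibull time-to-onset
(TTO) modelling with failure typing, Kaplan–Meier and Kruskal–Wallis
subgroup comparisons, and a risk-factor cascade (univariate screen → LASSO →
multivariable logistic regression). A synthetic report generator with
planted ground truth makes each stage testable without access to the real
databases, which cannot be redistributed.

## Ingestion and deduplication

The FAERS quarterly dialect is `$`-delimited ASCII, one file per entity
(DEMO, DRUG, REAC, OUTC, THER, INDI, RPSR). `parse_faers_tables()` resolves
header aliases, joins the entities by report id, and never fails a row on a
bad field: unparseable dates, ages and weights become missing and are
counted in a parse audit. Dates must be `YYYYMMDD` to support day-level
arithmetic; `YYYYMM`/`YYYY` values are retained as *partial* and treated as
missing wherever differences in days are needed — consistent with the very
high exclusion fractions seen in real TTO analyses. Ages are converted to
years from the FAERS unit codes (decades, months, weeks, days, hours);
weights coded in pounds are converted at 0.45359237 kg/lb. Drug names are
uppercased, whitespace-collapsed and stripped of a small editable table of
salt suffixes, because spontaneous-report drug fields are free text.

Deduplication follows the two FDA-style passes implemented in
`dedup_reports()`:

1. **Case-id pass.** Among records sharing a case id, keep the most recent
   FDA receipt date; ties go to the largest report id. A record with a
   missing receipt date can never be "most recent", so it loses against any
   dated record (and falls back to the id tiebreak otherwise).
2. **Demographic pass.** Among survivors, records identical on
   (age in years, sex, event date, sorted PT set, sorted primary-suspect
   drug set) collapse to the largest report id. The conventional manual rule
   uses only demographics and event dates; we add the sorted PT and suspect
   sets to the key so genuinely distinct reports that merely share age, sex
   and a date are not merged. The pass applies only to records whose age,
   sex and event date are all present: a missing field makes two reports
   non-comparable, and collapsing on incomplete keys would merge most of a
   database in which event dates are largely absent.

Both rules are audited (kept/removed counts per rule) and `dedup_reports()`
is idempotent.

## Case definition

A report is an EP case iff (i) at least one of its MedDRA preferred terms
belongs to the SMQ term set, and (ii) at least one drug on the report has
the primary-suspect role. Matching uses PT codes when the source carries
codes and falls back to case-insensitive exact name matching. The shipped
default (`smq_eosinophilic_pneumonia()`) contains the nine published PTs of
SMQ 20000159 — eosinophilic pneumonia (10014962), its acute and chronic
variants, Löffler's syndrome, pneumonitis, pulmonary eosinophilia,
hypereosinophilic syndrome, eosinophilic granulomatosis with polyangiitis
and eosinophilic pleural effusion. The licensed SMQ holds additional terms;
the table is user-extendable, and restricting the term set can only shrink
the case set (a tested monotonicity property).

## Disproportionality panel

For each drug, `contingency_table()` builds the report-level 2×2 table:
`a` case reports with the drug as primary suspect, `b` non-case reports
with it, `c` cases without it, `d` everything else. The counting unit is
the unique deduplicated report, not the drug–event pair. With
`N = a+b+c+d` and `s = sqrt(1/a + 1/b + 1/c + 1/d)`:

* `ROR = ad/bc`, 95% CI `exp(log ROR ± 1.96 s)`;
* `PRR = [a/(a+b)] / [c/(c+d)]` with the Pearson chi-square
  `N(ad−bc)² / [(a+b)(c+d)(a+c)(b+d)]` (no Yates correction by default —
  a flag restores it);
* relative reporting ratio `RRR = aN / [(a+b)(a+c)]`, information component
  `IC = log2 RRR` with `IC025 = IC − 1.96 s / ln 2` (delta method on the
  log2 scale);
* `EBGM = RRR` with `EBGM05 = exp(log EBGM − 1.64 s)` (one-sided 95%).

The IC and EBGM forms are deliberately the simplified observed-over-expected
versions rather than the full gamma–Poisson shrinkage machinery: published
panels of this kind print `IC ≈ log2 EBGM`, which is exactly the behaviour
of the simplified forms, and the shrinkage estimator adds hyperparameter
estimation that is out of scope here. The published IC025 values for this
condition are not reproducible by any standard closed form we are aware of,
so the delta-method bound above is the documented, configurable choice.
Zero cells leave the affected ratios flagged as undefined unless the
Haldane–Anscombe +0.5 correction is switched on (it is applied only when a
cell is zero, and never to the chi-square or the Fisher p).

Signal positivity uses the conventional any-of rule
(`signal_criteria()`): PRR method positive iff `n ≥ 3 ∧ PRR ≥ 2 ∧ χ² ≥ 4`;
ROR method positive iff the lower CI bound exceeds 1; IC method positive iff
`IC025 > 0`. Two useful analytic facts are enforced as tested invariants:
`sign(ROR−1) = sign(PRR−1) = sign(IC)` on every non-degenerate table, and
`ROR ≥ PRR ≥ 1` whenever `ROR > 1` (both follow from
`ROR/PRR = (1+a/b)/(1+c/d)`).

Each panel carries a two-sided Fisher exact p per drug with both Bonferroni
(`p_adj`, the screening default) and Benjamini–Hochberg (`p_fdr`, the
volcano-display default) adjustments, because both conventions are in use
and neither should be guessed away. `volcano_table()` emits
`(log2 ROR, −log10 p)` and also the swapped layout, since both axis
conventions appear in practice; exact zeros are floored at the smallest
representable double before the log. `compare_sources()` aligns two panels
computed under identical criteria and flags corroboration (positive in
both) and discordance; `pt_composition()` profiles the share of each
matched PT within drug classes (shares normalised within class).

## Time-to-onset

TTO is `event date − therapy start date` in days, computed per case and
primary-suspect drug. Cases missing day-level dates are excluded and
audited as *missing*; non-positive intervals (event on or before start) as
*invalid*; the audit conserves counts exactly
(`total = missing + invalid + retained`) and reports the exclusion
percentage rounded half-up to one decimal. Drug-level fits use one record
per (case, suspect drug); subgroup analyses (sex, age band, weight band)
use one record per case — the earliest-start row — so patients with several
suspect drugs are not double-counted.

`fit_tto_weibull()` fits scale α (days) and shape β by maximum likelihood
through `survival::survreg` with every event observed; right-censoring is
deliberately out of scope because only realized onsets are modelled. CIs
are delta-method intervals on the log-parameter scale. The model median is
`α (ln 2)^(1/β)` (a tested identity); the empirical median and IQR
(type-7 linear interpolation) are reported alongside, since onset tables
conventionally print empirical quantiles. Failure typing defaults to the
*point rule* — β < 1 early failure (decreasing hazard), β > 1 wear-out,
β = 1 random — because published classifications of this condition type
drugs whose shape CI straddles 1 by the point estimate; a CI-based rule is
available. Samples that are all identical have no finite shape MLE and come
back flagged degenerate. Fits with fewer than 3 observations are refused.

With no censoring the KM cumulative incidence equals the empirical CDF
(asserted pointwise in the tests); `km_curve()` still routes through
`survival::survfit` so the machinery extends to censored inputs.
`kw_test()` wraps the midrank, tie-corrected Kruskal–Wallis H with the
chi-square reference; an all-identical input across groups is defined as
H = 0, p = 1.

## Risk-factor cascade

`screen_candidates()` retains drugs with at least `min_n` case reports,
ROR lower bound above 1 and adjusted p below a ceiling. Published cascade
descriptions give two slightly different count thresholds ("at least
three" and "more than three"), so the screen defaults to `n ≥ 3` at the
descriptive stage and `n > 3` (`min_n = 4`) with `p < 0.01` at the
LASSO-entry stage; both are configurable.

`build_model_matrix()` produces one row per deduplicated report: a binary
EP-case outcome, screened-drug indicators, age (years), sex (male
indicator), weight (kg), and polypharmacy as the count of distinct drug
names on the report across all roles (the field lacks a standard
definition, so this simple one is documented and testable). Covariate
missingness uses complete-case analysis by default; an indicator mode
(median imputation plus a `*_missing` flag) exists because weight is absent
in roughly three quarters of real reports and complete-case analysis on
such data discards most of it.

`lasso_select()` runs the L1-penalized logistic path with 10-fold
cross-validation (`glmnet::cv.glmnet`), fold assignment stratified by
outcome so the rare cases appear in every fold, deterministic given the
seed. The CV criterion is the mean squared error of predicted
probabilities by default (deviance by flag) and λ is chosen at the CV
minimum. Continuous covariates are standardized internally; coefficients
are reported on the original scale. `fit_logistic()` then fits the
selected variables by maximum likelihood, reports Wald 95% CIs on the OR
scale and Bonferroni-adjusts p-values over the number of reported terms —
the denominator the final forest display actually shows, not the number of
screened drugs (configurable). Collinear columns are dropped with a
warning; quasi-separation (fitted probabilities within 1e-8 of 0/1 with a
diverging coefficient) flags the term and replaces its CI with an
infinite-interval marker rather than printing a meaningless Wald interval.

## Synthetic report generator

`simulate_reports()` emulates the seven-table quarterly structure with
known ground truth. Per report it draws demographics (sex 42/58 male/female
before missingness; age from the published band mixture; log-normal weight
around 75 kg; country mix matching the published distribution), exactly one
primary-suspect drug (a planted `drug_spec()` with probability equal to its
prevalence, otherwise a background drug), a Poisson(1.5) number of
concomitant background drugs, outcomes, and the target event by a
Bernoulli draw with

`logit p = logit(p0) + log m_d + γ'(x − x_c)`

where `p0` is the background event rate, `m_d` the planted odds multiplier
of the suspect drug and `γ` optional planted covariate log-odds effects
(zero by default), so the report-level odds of the event given drug versus
background equal `m_d` exactly when `γ = 0`. Cases draw their onset from
the drug's planted Weibull(β, α), rounded up to whole days, with
`event date = start date + TTO`; start dates accrue uniformly over
2014-01-01 … 2025-03-31, matching an eleven-year collection window.
Missingness is MCAR per field; the defaults follow the published
characteristics of the full database (37.6% missing age, 76.4% missing
weight, 15.2% unknown sex) and the date missingness (62% event, 60% start)
is set so that roughly 85% of cases lack complete day-level dates, the
completeness actually observed in practice. A configurable fraction of
dated cases (2% by default) has the event date moved before the start date
to exercise the invalid-TTO audit. Duplicate injection clones a fraction
of reports under a new report id, the same case id and a 30-day-later
receipt date, which the case-id dedup rule must remove exactly.

What the generator does **not** emulate: free-text drug-name noise,
multi-suspect reports (one primary suspect per synthetic report keeps the
2×2 counting unambiguous), reporting-culture differences between countries,
notoriety/channeling biases, and masking. Passing tests on synthetic data
therefore demonstrate statistical correctness of the machinery, not
robustness to real-world reporting biases.

## Verification scenarios and problem sizes

The test-suite scenarios are fixed design choices:

* **Closed-form panel**: 10,000 random tables against an independent
  log-space evaluation of the same formulas (agreement to 1e-10), plus an
  exhaustive Fisher-exact check against hypergeometric enumeration over
  *all* 635,375 tables with `N ≤ 60`, reduced by the row/column/transpose
  symmetry of the two-sided p.
* **Weibull recovery**: β ∈ {0.6, 0.77, 1.0, 1.23, 2.0} × α ∈ {25, 130},
  n = 1,000, 20 seeds; mean relative shape error ≤ 5% and failure typing
  must match the generating regime whenever |β − 1| ≥ 0.1.
* **Planted cascade**: n = 200,000 reports per seed, 30 null drugs plus
  three planted drugs with odds multipliers 12/5/3, 20 seeds. Prevalences
  are set to 0.01 so the weakest planted arm has ≈59 expected case
  reports: the scenario is powered so that a correct pipeline detects it
  with probability near 1, and a failure indicates a defect rather than
  borderline power. Covariate missingness is set low (5/10/2% for
  age/weight/sex) because the complete-case default would otherwise discard
  most rows before the regression stages. Detection, screening and LASSO
  selection must succeed in ≥ 18/20 seeds; the final Wald intervals must
  cover the planted ORs in ≥ 90% of the drug×seed intervals (95% intervals
  cannot be expected to cover three truths *jointly* in 18 of 20 seeds).
* **Kruskal–Wallis calibration**: 1,000 null replicates of three groups of
  30; the type-I error at the 5% level must stay within 3–7%.

These sizes keep the default suite within a few minutes on one CPU while
leaving each check statistically meaningful; they are stated here as the
package's own verification design.

## Known limitations

* The EBGM/IC pair is the simplified observed-over-expected formulation;
  full MGPS/BCPNN shrinkage is exposed nowhere and would change small-count
  panels most.
* No masking-effect correction, sequence-symmetry or time-scan methods.
* The Weibull stage has no censoring, competing risks or interval-censored
  support; onset is modelled only for realized, dated events.
* Logistic results are associations in a reporting database, not causal
  effects; notoriety and channeling biases propagate into any such panel.
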