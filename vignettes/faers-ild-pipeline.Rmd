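---
title: "Methods: disproportionality analysis of ALK-inhibitor interstitial lung disease in FAERS-style data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality analysis of ALK-inhibitor interstitial lung disease in FAERS-style data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
library(data.table)
```

## The problem

Interstitial lung disease (ILD) is an uncommon but potentially fatal
toxicity of the five ALK tyrosine kinase inhibitors (crizotinib,
ceritinib, alectinib, brigatinib, lorlatinib) used in ALK-positive
non-small-cell lung cancer. Because randomized trials are too small to
characterize rare toxicities, post-marketing surveillance relies on
spontaneous-report databases such as the FDA Adverse Event Reporting
System (FAERS), distributed as quarterly `$`-delimited ASCII tables
(DEMO, DRUG, REAC, THER, INDI, OUTC). This package implements the full
analysis chain for such data — cleaning, case finding, disproportionality
signal detection, onset and dose characterization, and logistic risk
modelling — together with a synthetic FAERS generator that plants known
structure, so every stage can be validated against ground truth.

Spontaneous reports have no denominator: one cannot estimate incidence,
only *reporting disproportionality* — whether a drug–event pair is
reported more often than the rest of the database predicts. All
interpretation below is subject to that limit.

## Data model and cleaning

A `faers_bundle` holds the six linked tables keyed by report id
(`primaryid`); `caseid` groups versions of the same case
(initial/follow-up). Cleaning proceeds in three stages.

**Single missing-value imputation.** For a case with several versions, a
version missing exactly one of {event date, age, sex, reporter country}
receives that field's maximum value among versions of the same case that
have all four fields populated. Versions missing two or more fields are
never imputed. "Maximum" is numeric for age (after unit normalization:
decades ×10, months ÷12, weeks ÷52.18, days ÷365.25) and lexicographic
for the other fields, which is a deliberate operationalization: the rule
must be a total order on strings, and lexicographic order on `YYYYMMDD`
dates coincides with chronological order.

**Two-step de-duplication.** Step 1 collapses rows identical on (case
id, initial/follow-up code, event date, age, sex, reporter country,
sorted drug-name set, sorted outcome set) to the *most recent* version,
operationalized as the largest report id — FAERS assigns ids
monotonically, and this stays well-defined when dates are partial. Step
2 then collapses rows identical on (event date, age, sex, reporter
country, drug set, sorted reaction set) across cases. Step 1 must
precede step 2 because cross-case matching is only meaningful after each
case is reduced to one representative. Missing key fields compare equal
to missing; ties never depend on row order, so the retained set is
invariant under shuffling of the input.

Demographic-key dedup knowingly removes some genuinely distinct reports
that coincide on all key fields; at 50,000-report scale the synthetic
data loses ~9% this way, comparable to the ~14% removed from the real
15.6M-report corpus. The truth ledger of the generator lets tests verify
the removal counts exactly against an independent enumeration.

**Exclusions.** Reports with known age under 18 years are removed;
unknown-age reports are retained (the rule applies to known ages only —
demographic tables in this field routinely carry an "Unknown" age row).
The comparator universe for signal detection is the full cleaned
database; the *study set* (primary-suspect ALK TKI reports, matched
case-insensitively against a bundled generic+brand synonym table) is
used for demographics, onset and risk modelling.

## Case finding

Cases are identified by the Standardised MedDRA Query "Interstitial lung
disease" (SMQ 20000042) at the preferred-term level. The bundled
definition carries the six core narrow PTs (acute interstitial
pneumonitis 10066728, idiopathic interstitial pneumonia 10078268,
interstitial lung abnormality 10087834, interstitial lung disease
10022611, pneumonitis 10035742, pulmonary fibrosis 10037383) plus
configurable broad extras; the full licensed MedDRA hierarchy is out of
scope. A report is a case iff at least one of its reaction PTs is in the
SMQ, and it contributes at most 1 to any contingency cell regardless of
how many matching PTs it lists — report-level counting is what makes
"n cases" interpretable. Per-PT analyses count the same way per PT.

## Disproportionality statistics

For one drug–event pair, with `a` reports carrying both, `b` the drug
without the event, `c` the event without the drug, `d` neither, and
`N = a+b+c+d`, `E = (a+b)(a+c)/N`:

* **ROR** `= ad/bc`, with 95% CI
  `exp(log ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`. A zero cell makes the
  estimate undefined; by default 0.5 is added to every cell of such
  tables (configurable), otherwise an `NA` marker is returned.
* **PRR** `= [a/(a+b)] / [c/(c+d)]` with the Pearson chi-square
  `N(ad−bc)² / [(a+b)(c+d)(a+c)(b+d)]`, un-corrected by default; a Yates
  switch exists for sensitivity analyses.
* **IC** `= log2[(a+0.5)/(E+0.5)]` with the lower credibility bound
  `IC025 = IC − 3.3(a+0.5)^{−1/2} − 2(a+0.5)^{−3/2}`; the +0.5 shrinkage
  makes it defined for every table.
* **EBGM**: the posterior geometric mean of the reporting-rate ratio
  λ under the gamma-Poisson shrinker below, with EB05/EB95 the posterior
  5th/95th percentiles.

The default joint signal criterion is `a ≥ 3` AND ROR lower bound > 1
AND `PRR ≥ 2` with `χ² ≥ 4` AND `IC025 > 0` AND `EB05 > 2`; each
algorithm's flag is also reported individually. These are the standard
thresholds of the field; no published numeric criterion is being
reproduced, and they are configurable.

## The gamma-Poisson shrinker

Counts are modelled as `a_i ~ Poisson(λ_i E_i)` with
`λ ~ p·Gamma(α₁, β₁) + (1−p)·Gamma(α₂, β₂)` (shape/rate). Marginally
`a_i` is a mixture of two negative binomials; the prior is fitted by
maximum marginal likelihood on all (primary-suspect drug, PT) pairs of
the cleaned database, using BFGS on log/logit-transformed parameters
from eight deterministic starts (the classical start
`(0.2, 0.1, 2, 4, p=1/3)` plus spread-out alternatives). The posterior
for each pair is again a two-component gamma mixture with conjugate
updates `(α_k + a, β_k + E)` and weights proportional to prior weight ×
NB marginal; `EBGM = exp(E[ln λ])` and the quantiles come from
root-finding on the posterior mixture CDF. Tests verify the posterior
summaries against a brute-force quadrature of
`prior(λ)·Poisson(a; λE)` on a fine log grid — an oracle that never uses
the conjugate shortcut.

Two behaviors are worth knowing. First, the mixture labels are not
identifiable (swapping components with `p ↦ 1−p` changes nothing
posterior-relevant); tests compare only label-invariant quantities.
Second, when the database's true reporting-rate ratios take only a few
discrete values — as in synthetic data with a single planted RR — the ML
prior legitimately degenerates toward point masses (α, β of order 10⁸),
and posterior intervals become very tight. That is the correct ML
solution for such data, confirmed by the quadrature oracle; real
databases, with genuinely heterogeneous λ, yield diffuse priors.

## Onset and cumulative dose

Time to onset is the event date minus the *earliest* therapy-start date
of the suspect drug, in whole days; negative intervals are logged
anomalies and become missing. Partial dates (`YYYYMM`, `YYYY`) are
imputed to their midpoint (15th; July 1st), which minimizes expected
absolute error; a precision flag is retained. Quartiles use linear
interpolation on the sorted sample (`stats::quantile` type 7) — the
convention is a choice, stated here because published onset quartiles
rarely say which rule produced them. "Within 4 weeks / 8 weeks" is
exactly ≤ 28 / ≤ 56 days, over records with known onset only.
Cumulative dose at onset is `daily dose (mg/day) × TTO (days) / weight
(kg)`; the formula is an inference from the reported mg/kg unit, since
no computation is ever printed alongside such figures.

## Risk model and nomogram

Among study reports, the outcome is the SMQ case flag, and covariates
are binary indicators: age group (18–64 reference, 65–84, ≥85 — age 85
joins the upper group, resolving the usual "65–84 / >85" boundary gap —
and unknown), sex (female; unknown), drug (lorlatinib as reference, so
four indicators), seven concomitant diseases, and eight concomitant
drugs. FAERS has no comorbidity table, so concomitant diseases are
derived from the indication PTs of *non-suspect* drug rows — an
interpretation, and the main structural assumption of this module.

Univariate ORs are cross-product odds ratios with Woolf (log-Wald) CIs,
identical to single-covariate logistic fits (an identity tested to
6 decimals). The multivariate model is maximum-likelihood logistic
regression via IRLS (`stats::glm`), with Wald CIs and p-values. Wald
tests can disagree with likelihood-ratio or score tests for the same OR,
so p-values from different software are not directly comparable.
A covariate whose exposed stratum contains only cases or only non-cases
has an infinite MLE; `estimable_covariates()` screens these out, and
`fit_risk_model()` additionally drops covariates flagged by separation
or exact collinearity and refits — the desk-scale analogue of fitting
only an estimable covariate subset.

The nomogram assigns covariate `i` the point scale
`points_i(x) = 100·(β_i x − min β_i x) / M`, `M = max_j |β_j|·range_j`,
so points are non-negative and the most influential covariate spans
exactly 100 points; total points map to probability through the inverse
logit of the reconstructed linear predictor. This mapping is exact, not
an approximation: `predict_risk()` equals the direct logistic prediction
to machine precision (tested at 10⁻⁶ over random profiles).

## The synthetic generator

`synth_config()` / `simulate_faers()` emulate: multiple case versions
per case (exact-duplicate versions at `duplicate_rate`, follow-up
versions with equal-or-larger completeness at `followup_rate`), partial
and missing demographics at configurable per-field rates, one
primary-suspect drug per report with concomitants and their indication
PTs, PT-coded reactions drawn per (drug, PT) with probability
`min(1, rr × background)`, therapy starts inside the quarter, event
date = start + a per-drug log-normal onset draw, label daily doses, and
outcome codes. Every report version's pre-noise truth is recorded in a
ledger for exact downstream assertions. A report that draws no reaction
receives one common background PT (≥1% background rate),
drug-independently — a spontaneous report always lists at least one
event, and restricting fillers to common PTs keeps rare-event rates at
their configured values. A fraction of concomitant INDI rows
(`offlabel_indication_rate`, default 0.15) carries an
unspecified-indication PT, as in real reports, which also keeps disease
indicators from being deterministic functions of drug indicators.

Defaults were chosen once as the study conditions: the five ALK TKIs at
primary-suspect shares proportional to their real report volumes, scaled
so that 200,000 synthetic reports contain ≈20,000 TKI reports; ILD SMQ
PTs at ~1% total background reporting probability; per-drug onset
medians 29/70/49/7/36 days with `sdlog = 1.4`; label daily doses
500/750/1200/180/100 mg; adult-heavy age mixture with a 2% pediatric
fraction; field missingness between 5% and 25%. All planted relative
risks default to 1.

What the generator does **not** emulate: free-text drug-name noise and
misspellings (matching is exact after case/trim normalization), the
MedDRA hierarchy above PT level, correlated covariates and confounding
(concomitant drugs are independent of the outcome unless planted),
reporting-rate heterogeneity beyond the planted values, secular trends
across quarters, and real RPSR/literature-source structure. Passing
tests therefore demonstrate *algorithmic correctness under known
structure* — not that the pipeline's operating characteristics transfer
to the messier real corpus.

## Numerical choices and problem sizes

Determinism: all generation flows from a single integer seed through R's
Mersenne-Twister; identical seed and config give byte-identical files.
MGPS convergence uses `optim` BFGS with relative tolerance 10⁻¹²,
parameters capped at e⁶⁰ to avoid overflow; posterior quantiles use
`uniroot` at tolerance 10⁻¹⁰. The test and acceptance runs use problem
sizes chosen to make the checks sharp but quick: 20 null databases and
20 planted-signal databases of 50,000 reports for calibration and power,
logistic recovery at n = 20,000 over 20 seeds (maximum absolute
coefficient bias < 0.05), 1,000 random (a, E) pairs for the EBGM
quadrature comparison at 10⁻³, and 100 random profiles for the nomogram
round-trip at 10⁻⁶.

## Known limitations

Disproportionality is not risk: no incidence, no causality. The
cleaning rules (largest-id recency, lexicographic maxima, midpoint
dates) are documented operationalizations of verbally specified
procedures, and other reasonable operationalizations would retain
slightly different report sets. The concomitant-disease construction
leans on indication coding, which real reporters often omit. The full
licensed MedDRA SMQ contains more PTs than the bundled core set, so
real-data case counts depend on the definition file supplied. And the
synthetic world is a validation harness, not a simulation of FAERS: any
quantitative agreement between its outputs and published full-corpus
figures is a design choice of the generator defaults, not evidence about
the real database.
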