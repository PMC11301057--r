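---
title: "Disproportionality signal mining on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`faersignal` implements a desk-scale pharmacovigilance screening pipeline for
spontaneous adverse-event reports in the FAERS quarterly ASCII dialect. The
statistical object throughout is the 2×2 contingency table for one
(drug, event) combination over the deduplicated database:

|                     | event of interest | all other events |
|---------------------|-------------------|------------------|
| target-drug reports | a                 | b                |
| all other reports   | c                 | d                |

The counting unit is the **unique (report, preferred term) pair**: a report
listing the same reaction twice contributes one pair; a report with three
distinct reactions contributes three. `N = a + b + c + d` is therefore the
number of unique pairs, not the number of reports, and the expected count
under independence is `E = (a + b)(a + c) / N`.

Spontaneous reporting has no denominator of exposed patients, so none of the
statistics below estimates incidence. They measure *disproportionality*: how
over-represented a (drug, event) pair is relative to the rest of the database.

# Ingestion and cohort construction

* **Parsing.** The seven quarterly tables (DEMO, DRUG, REAC, OUTC, RPSR,
  THER, INDI) are `$`-delimited with a header line and no quoting. The header
  drives column order; required columns are validated per table and extra
  columns are preserved but ignored. Fields stay raw strings at this layer so
  no row can be lost silently to a type-parse failure. Files that are not
  valid UTF-8 are re-encoded from latin-1.
* **Deduplication.** FAERS carries multiple versions of a case. Per `caseid`
  the report with the latest `fda_dt` survives; ties break to the largest
  numeric `primaryid`. The operation is idempotent and order-insensitive.
* **Cohort.** A report enters the cohort when a drug record with role code
  `PS` (primary suspect, configurable) matches any of the target-drug name
  terms after case normalization and punctuation collapse. All other reports
  form the background.
* **Event coding.** Reaction preferred terms (PTs) are case/whitespace
  normalized and mapped to system organ classes (SOCs) through a user-supplied
  two-column dictionary (MedDRA content is licensed and never shipped).
  Unmapped PTs are kept under an explicit `UNMAPPED` class and tallied, never
  dropped.

# The four statistics

For each term with at least one cohort pair (`a ≥ 1`):

**Reporting odds ratio (ROR).** `ROR = ad / bc`, with the Woolf 95% interval
`exp(ln ROR ± 1.96 · sqrt(1/a + 1/b + 1/c + 1/d))`. Undefined (returned as
`NA`, "non-evaluable") when any cell is zero; no Haldane 0.5 continuity
correction is applied, because the retention rule already requires `a ≥ 3`
and a corrected estimate would silently change every other table too.

**Proportional reporting ratio (PRR).** `PRR = [a/(a+b)] / [c/(c+d)]`, with
the Pearson chi-squared statistic
`χ² = N(ad − bc)² / [(a+b)(c+d)(a+c)(b+d)]`. A Yates continuity correction is
available but off by default. `PRR` needs all four margins positive.

**Bayesian confidence propagation neural network (BCPNN).** The information
component `IC = log2 P(drug, event) / (P(drug) P(event))` is estimated by the
closed-form posterior expectation of Bate et al. (1998), with the standard
weak priors `α₁ = β₁ = 1`, `α = β = 2`, `γ₁₁ = 1` and the prior-balancing
`γ = γ₁₁ (N + α)(N + β) / [(a + b + α₁)(a + c + β₁)]`. The lower credibility
bound is `IC025 = E(IC) − 2·sd(IC)` from the closed-form variance. The closed
form is a log-of-expectation approximation whose bias against the exact
posterior mean of the IC is of order `1/a`; it is accurate in the counting
regime where the retention rule operates (`a ≥ 3`, and in practice tens of
pairs) but measurably biased (more than 0.05 bits) for `a` near 10. The test
suite therefore checks it against a Monte-Carlo posterior oracle on tables
with `a ∈ [20, 200]`.

**Multi-item gamma Poisson shrinker (MGPS).** Counts are modeled as
`a ~ Poisson(λE)` with the DuMouchel (1999) two-component gamma mixture prior
on the relative report rate λ. The five hyperparameters are fitted by
maximizing the negative-binomial mixture marginal likelihood over all tables
of the screen. The posterior is again a two-gamma mixture;
`EBGM = exp(E[ln λ])` uses the digamma closed form, and `EB05` (the posterior
5th percentile) is found by root-finding on the posterior CDF.

## Retention rule

A term is *retained* (default: all four must hold) when

* ROR: `a ≥ 3` and the lower Woolf bound `> 1`;
* PRR: `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`;
* BCPNN: `IC025 > 0`;
* MGPS: `EB05 > 2`.

An "any k of four" rule is configurable. `NA` statistics never satisfy a
criterion. All thresholds live in `signal_criteria()` and are recorded in the
pipeline manifest.

# Descriptive outputs

* **Cohort description.** Sex, age bands (default cuts 18 and 65 years, age
  converted from FAERS units including decades), outcome codes, reporter
  occupation, country and indications. Percentages are rounded **half-up** to
  2 decimals (the convention of regulatory tables; R's `round()` rounds half
  to even) over the cohort-size denominator; indication percentages use total
  indication entries.
* **Time to onset (TTO).** Days from the earliest valid therapy start date of
  the matched suspect drug to the event date. Records are excluded — with an
  explicit status, never silently — for missing dates, partial dates
  (anything but valid `YYYYMMDD`), or an event before therapy start. Median
  and quartiles use type-7 (linear interpolation) quantiles; onset bins are
  closed integer-day intervals 0–30, 31–60, 61–90, 91–180, 181–365, >365.
* **Subgroups.** For sex and age-band strata the *entire database* (cohort and
  background) is restricted to the stratum and the screen re-run, so the
  background matches the stratum. Strata whose cohort falls below a floor
  (default 10 reports) are excluded with a notice.

# Synthetic data generator

`generate_faers()` writes a database in the exact quarterly dialect plus the
ground truth needed to validate every stage, so the pipeline can be tested
end to end without the multi-gigabyte FAERS download.

* Drug and event marginals are Zipf(1.5) — spontaneous-report frequencies are
  heavy-tailed.
* Events per report follow a truncated geometric with mean 2.5 (capped at
  10).
* Elevated-risk pairs are *implanted* by multiplying the odds of the chosen
  event in target reports by a factor ρ and renormalizing. Implants are
  placed at rare-tail event indices (the default recovery study uses indices
  25, 35, 45 of 100) so the renormalization barely perturbs the other event
  probabilities and the measured ROR stays close to ρ; implanting at head
  indices would saturate the target reports' event distribution and decouple
  ρ from the observed odds ratio.
* Onset days are log-normal (default median 44 days, `sdlog` 1.17); event
  dates are then corrupted at configurable rates into partial or missing
  dates.
* Duplicates re-emit a case under a fresh `primaryid` with a later `fda_dt`,
  so the *duplicate* is the intended survivor — this makes the deduplication
  test sensitive to keeping the wrong version.
* The generator saves and restores `.Random.seed`, so it never disturbs the
  caller's RNG stream, and identical configurations write byte-identical
  files.

Two fixed study designs are used by the test suite: a **null study**
(5,000 reports, no implants) for calibration of the four-way retention rule,
and a **recovery study** (20,000 reports, 6% target share, three implants at
ρ = 10, designed so implanted `a`-counts are ≥ 30). Both were fixed before
any results were inspected and are asserted at their design tolerances, not
tuned to pass.

# Numerical choices

* Half-up rounding is implemented with an epsilon nudge before `round()`.
* All cell counts are coerced to double before products such as `ad − bc`
  (integer overflow is reachable at FAERS scale).
* The MGPS marginal likelihood is maximized by Nelder–Mead on log/logit
  transformed hyperparameters from five fixed starting points (DuMouchel's
  published start plus four alternates), then polished by restarting from the
  incumbent until the optimizer reports convergence. The fit is deterministic
  and does not touch the RNG.
* `EB05` uses Brent root-finding (`uniroot`, tolerance 1e-10) on the
  posterior mixture CDF with geometric bracket expansion.
* Quantiles are type 7 everywhere; the choice is stated because medians and
  quartiles of small cohorts depend on it.

# Limitations

* Synthetic reports are conditionally independent given the implant design:
  no drug–drug interactions, polypharmacy correlation, indication
  confounding, or secular reporting trends (all reports share one study
  window). Null calibration on this generator is therefore optimistic
  relative to real FAERS, where confounding inflates false positives.
* The BCPNN closed form is biased at very small `a` (see above); its retained
  set can differ from an exact-posterior implementation near the threshold.
* The two-gamma MGPS prior is weakly identified when the true rate
  distribution has a single component; fitted component parameters can split
  or swap even when the fitted prior's moments are correct. Screens with very
  few tables (fewer than 10) warn that hyperparameter estimates are
  unstable.
* Disproportionality is hypothesis-generating only: retained terms are
  signals for pharmacological and clinical review, not incidence or causal
  estimates.
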