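# hurdlecohort

Matched-cohort analysis of healthcare utilisation and cost from
electronic-health-record (EHR) style event streams, built around two-part
(hurdle) models for zero-inflated, right-skewed outcomes.

The package is aimed at health-services researchers and epidemiologists who
study how a diagnosis (the motivating case is long COVID) changes how often
people use primary and secondary care, and what that costs a health system.
It provides the whole analysis path as tested, reusable functions:

1. **Synthetic cohort generation** with known ground-truth effects, so every
   downstream stage can be validated without access to patient data.
2. **Cohort construction**: eligibility filtering, 1:5 exact matching on
   age, sex and region with seeded tie-breaking, index-date inheritance, and
   censored follow-up.
3. **Outcome construction**: per-care-type visit counts with same-day
   deduplication, and cost assembly from unit costs (GP consultations at a
   flat £41, prescriptions priced per BNF chapter, recorded secondary-care
   costs).
4. **Two-part modelling**, **marginal standardisation**, a
   **difference-in-difference (DID)** historical comparison, and a
   sensitivity suite (cost imputation, stratified analyses with
   likelihood-ratio interaction tests, cohort restrictions).

## The model

Healthcare visit counts `Y` and costs are zero-inflated and right-skewed,
so each outcome is modelled in two parts:

* **Part 1 (any use).** A logistic regression for the probability of any
  use, `logit P(Y > 0) = x'γ`. The exponentiated exposure coefficient is the
  **odds ratio (OR)** of using healthcare at all.
* **Part 2 (amount of use among users).** For counts, a zero-truncated
  NB2 regression fitted by maximum likelihood,

  ```
  P(Y = y | Y > 0) = f(y; μ, α) / (1 − f(0; μ, α)),   y = 1, 2, …
  log μ = x'β + log(person-years),  Var(Y*) = μ + αμ²
  ```

  with the family chosen by an overdispersion check (Poisson residual
  deviance / df > 1 ⇒ negative binomial). The exponentiated exposure
  coefficient is the **rate ratio (RR)** among users. For costs, a Gamma
  GLM with log link and the same person-time offset gives the **cost
  ratio**.
* **Absolute scale.** Predictions multiply the two parts,
  `E[Y] = P(Y > 0) × E[Y | Y > 0]`, averaged over the cohort's covariate
  distribution with exposure set counterfactually (marginal
  standardisation), reported per person-year with percentile
  cluster-bootstrap intervals resampled at the matched-set level.
* **DID.** The historical comparison stacks a fixed pre-pandemic window
  (March 2019 – March 2020) with post-index follow-up, adds a
  `group × period` interaction to both parts, and reports
  `(exposed post − exposed pre) − (comparator post − comparator pre)` on
  the absolute predicted scale.

The zero-truncated likelihood, its analytic score and observed-information
covariance are implemented in the package (`truncated_count_logpmf()`,
`fit_truncated_glm()`); standard GLMs use `stats::glm`.

## Worked example

```r
library(hurdlecohort)

params <- simulation_params(n_exposed = 500, seed = 42)
cfg    <- pipeline_config(sim_params = params, seed = 42)
sim    <- simulate_cohort(params, cfg)
rows   <- build_analysis_rows(sim$members, sim$follow_ups, sim$events,
                              sim$patients, sim$unit_costs, "contemporary")
fit    <- fit_two_part(rows, model_spec(outcome = "total_visits"))
fit
#> Two-part model for 'total_visits' (2138 rows, 1729 non-zero; second part: negbin)
#>             part    measure estimate ci_low ci_high  se_log
#>         binomial odds_ratio    9.458  5.345  16.736 0.29116
#>  truncated_count rate_ratio    2.042  1.855   2.248 0.04905

predict_average(fit, rows, "exposed")     # 54.17 visits per person-year
predict_average(fit, rows, "comparator")  # 21.22 visits per person-year
```

Read: exposed patients have 9.5 times the odds of any healthcare contact in
the year after their index date, and — among people with at least one
contact — 2.04 times the visit rate, which standardises to 54.2 vs 21.2
visits per person-year on the absolute scale. The generator's closed-form
oracle (`implied_effects(sim$truth, sim$members)`) gives the matching truths
(OR 7.76, deduplicated conditional RR 1.95) against which the fits are
tested; at this small cohort size the estimates sit within sampling error
of them.

`run_pipeline(pipeline_config(...))` chains all stages — matching,
outcomes, every fit, predictions, DID, descriptives and sensitivity
analyses — and writes each intermediate as CSV plus a run log.
A command-line wrapper is installed at
`system.file("scripts", "cohort-pipeline.R", package = "hurdlecohort")`.

## File formats

All tables are comma-separated UTF-8 with a header row; dates ISO-8601;
intervals half-open `[start, end)`; currency in pounds.

| file | columns |
|---|---|
| patients | `patient_id, age, sex, region, ethnicity, imd_quintile, bmi_category, asthma, mental_health, n_comorbidities, prior_covid_hospitalisation, n_vaccine_doses, positive_test_before_index, registration_start, registration_end, death_date, longcovid_diagnosis_date, longcovid_resolved_date, practice_id` |
| events | `patient_id, date, care_type (gp, prescription, ae, admission, outpatient), code (BNF chapter for prescriptions), cost, discharge_date` |
| unit costs | `item (gp_consultation or BNF chapter), cost` |
| matched sets | `set_id, patient_id, group, index_date` |
| analysis rows | one person-period per row: follow-up days, per-type counts, cost components, covariates |
| estimates | `outcome, family, part, term, estimate, se, ci_low, ci_high, scale` |
| predictions | `outcome, group, predicted_mean, ci_low, ci_high, n_bootstrap` |

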