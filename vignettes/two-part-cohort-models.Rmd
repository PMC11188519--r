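---
title: "Two-part models for matched-cohort healthcare utilisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part models for matched-cohort healthcare utilisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how and why the package models matched-cohort
healthcare utilisation the way it does: the statistical model and its
assumptions, what the synthetic-data generator does and does not emulate,
the numerical choices inside the estimators, and the design decisions taken
where more than one defensible option existed.

## The estimation problem

We compare healthcare utilisation (visit counts across five care types:
GP consultations, prescriptions, A&E attendances, inpatient admissions,
outpatient appointments) and costs between people carrying a diagnosis of
interest ("exposed", the motivating case being long COVID) and matched
comparators, over a 12-month window after a shared index date. Visit and
cost distributions in such cohorts are zero-inflated and right-skewed: many
people have no contact at all, and the non-zero tail is long. A single GLM
handles this badly, so each outcome is modelled in two parts:

1. a **binomial part** for the probability of any use,
   $\mathrm{logit}\, P(Y>0) = x'\gamma$;
2. a **conditional part** for the amount of use among users — a
   zero-truncated count regression for visits, a Gamma GLM with log link
   for costs — with $\log$ person-years as an offset.

The exposure coefficients of the two parts are reported as an odds ratio
(any use) and a rate ratio or cost ratio (amount among users). Absolute
quantities are recovered by multiplying the parts and averaging over the
cohort's covariate distribution with exposure set counterfactually
(marginal standardisation), reported per person-year.

### The truncated count part

Among users the count follows a zero-truncated NB2 distribution,
$P(Y=y \mid Y>0) = f(y;\mu,\alpha)/(1-f(0;\mu,\alpha))$ with
$\mathrm{Var} = \mu + \alpha\mu^2$, or its Poisson limit ($\alpha = 0$).
The family is chosen by the conventional overdispersion screen: a Poisson
regression is fitted to the non-zero rows and the ratio of residual
deviance to residual degrees of freedom compared with a threshold of
exactly 1.0 (configurable; values near 1 indicate Poisson-like variation,
larger values extra-Poisson variation, and healthcare counts essentially
always exceed it).

No installed package provides truncated count GLMs, so the likelihood is
implemented here. Numerical choices:

* The truncation constant is computed as
  $-\log f(0) = \theta \log(1+\mu/\theta)$ with $\theta = 1/\alpha$ via
  `log1p`, and $\log(1-f(0))$ via the standard stable `log(1-exp(-x))`
  split, so the log-pmf is accurate for $\mu$ up to $10^4$ and $y$ up to
  $10^5$. For $\alpha < 10^{-3}$ the NB log-pmf switches from
  `stats::dnbinom` to an exact product form
  ($\sum_{k<y}\log(1+k/\theta) - (\theta+y)\log(1+\mu/\theta) + \dots$),
  because the `lgamma` difference in the usual parameterisation loses
  absolute precision when $\theta$ is huge; this keeps the Poisson limit
  smooth to the order of the true continuity gap, which is
  $O(\alpha y^2/2)$.
* The MLE maximises the joint likelihood in $(\beta, \log\theta)$ by BFGS
  with the analytic score; the dispersion is estimated jointly rather than
  profiled. Initialisation is an untruncated Poisson fit plus a
  Pearson-residual moment estimate of $\alpha$. Convergence demands a
  score norm below $10^{-8}$ per observation (one polish pass is allowed);
  an $\alpha$ estimate below $10^{-6}$ is treated as the Poisson boundary
  and refitted as truncated Poisson with a warning.
* The covariance is the inverse observed information, obtained by central
  differences of the analytic score at the optimum; Wald intervals are
  symmetric on the log scale, the convention in this literature.

The truncated-NB conditional mean used in predictions is
$\mu/(1-f(0;\mu,\alpha))$; tests verify it against brute-force summation
of $y \cdot P(y)$, and the log-pmf against brute-force normalisation of
the untruncated pmf, to $10^{-8}$ and $10^{-10}$ respectively.

### Offsets and the first part

Log person-years enter the count and cost parts as offsets, so their
linear predictors are log rates. The binomial part is fitted **without**
an offset: an offset on the logit scale has no person-time interpretation,
and the first part is a probability over the observation window, not a
rate. This is a deliberate reading recorded here because wording about
offsets in "both models" is ambiguous in this literature; we take it to
mean the two second-part models (counts and costs).

Missing covariate values (ethnicity, IMD quintile, BMI) become an explicit
`"(missing)"` level by default rather than dropping rows — in realistic
EHR cohorts ethnicity alone can be ~15% missing, and complete-case
deletion would distort the cohort. Complete-case analysis is available
via `model_spec(missing_as_category = FALSE)`.

## Cohort construction

* **Eligibility**: adults (18+) registered for at least 90 days before the
  study start (1 November 2020, both configurable) and still registered at
  it; the 90-day boundary is inclusive. Patients with incomplete
  registration records are excluded with a counted reason, not an error.
* **Matching**: each exposed person is matched to up to five comparators
  with identical integer age, sex and region. The matching algorithm is
  necessarily an assumption (observational studies rarely publish theirs):
  we match **without replacement**, processing exposed persons in
  ascending index-date order, sampling among eligible candidates with a
  seeded RNG so runs are reproducible. Exact integer age is used because
  it reproduces the hallmark of this design — essentially identical age
  distributions between arms. Sets with 1–4 comparators are retained;
  exposed persons with no available comparator are dropped with a count.
  Under finite supply the total number of comparators is slightly below
  five per exposed person, which is the expected signature of
  without-replacement matching.
* A person diagnosed later in the study **may serve as a comparator
  before their diagnosis**; they are censored at diagnosis in that role
  and additionally head their own exposed set. This mirrors how such
  cohorts are built in practice and has a visible consequence for the
  estimands (below).
* **Follow-up** runs from the index date to the earliest of death, end of
  registration, receipt of a resolution code (exposed only), the
  comparator's own diagnosis, the administrative end (31 January 2023),
  and the 365-day window end. Intervals are half-open `[start, end)`; day
  counts are `end − start`. On exact ties the cause precedence is death,
  deregistration, resolution, comparator diagnosis, administrative end,
  window end — except that a registration running to or past the
  administrative end is labelled administrative censoring, not
  deregistration. Zero-length intervals (e.g. death on the index date)
  are flagged and excluded from modelling rather than erroring.

## Outcome construction

For each care type, the visit count is the number of **distinct event
dates** in the window — multiple same-day contacts of one type (several
prescriptions issued together being the canonical case) count once.
Deduplication is within type only: a GP visit and an A&E attendance on one
day are two visits. Admissions count only when the stay exceeds one day,
operationalised as discharge date strictly after admission date. The
within-type rule is applied uniformly across care types; whether real
analyses deduplicate A&E or outpatient contacts the same way is usually
unstated, and uniformity is the defensible default.

Costs deliberately follow a different counting rule for prescriptions:
GP cost is the **deduplicated** visit count × £41 (the 2021/22 national
average consultation cost), while prescription cost is the **raw** item
frequency per BNF chapter × the chapter unit cost — both rules are stated
in the source methodology and they genuinely differ, so both are
implemented as written. Secondary-care costs are sums of recorded event
costs; rows with any missing secondary cost are flagged, and the
sensitivity suite imputes missing costs with the care-type-specific mean
of observed per-event costs ("the mean cost for one visit" read as the
per-event mean, computed across persons).

The historical window is fixed at `[2019-03-01, 2020-03-01)` for all
patients regardless of index date; historical rows exist only for members
registered from the window start through their index date, and persons
dying mid-window contribute truncated person-time.

## The synthetic cohort generator

The generator exists so that every stage has a testable ground truth. Its
generative model, per patient and observation window:

* a single hurdle indicator $H \sim \mathrm{Bernoulli}(p_g)$ for any
  healthcare use ($p$ group-specific);
* given $H=1$, a zero-truncated NB2 total count with
  $\log\mu = \log(\text{base rate}) + \log(\text{RR})\cdot\text{exposed}
  + \delta\cdot\text{exposed}\cdot\text{contemporary} + x'\eta
  + \log(\text{person-years})$;
* the total split multinomially across the five care types with fixed
  shares, dates uniform in the window; Gamma per-event costs on
  secondary-care events (exposed means scaled by the cost ratio), a small
  fraction blanked to missing; admissions always emitted with stays of
  more than one day.

A design decision worth recording: an earlier sketch used **independent
hurdles per care type**. That form cannot support the totals-based tests —
with independent per-type hurdles, $P(\text{any use})$ is driven to ~1 for
realistic per-type probabilities (so odds ratios of the observed magnitude
are unreachable) and the totals model is misspecified (a sum of
independent hurdle-ZTNBs is not hurdle-ZTNB), which would put asymptotic
bias, not sampling error, into the recovery tests. The shared-hurdle /
multinomial-split form makes the totals estimator correctly specified with
closed-form truths, at the cost of per-type counts being thinned totals
rather than independent processes; per-type models are still fitted and
reported, but parameter-recovery claims attach to the totals.

Default parameters are fixed study conditions, chosen once: hurdle
probabilities 0.961 / 0.75 (implying a first-part OR near 8.3), a
conditional rate ratio of 1.49 applied in both periods, a DID multiplier
of 1.43 on the exposed contemporary rate, cost ratio 1.44 on secondary
per-event costs, NB2 dispersion $\alpha = 0.8$ (strongly overdispersed,
geometric-like), a comparator rate of 22 events per person-year, care-type
shares dominated by GP contacts and prescriptions, ~2% missing secondary
costs, and covariate log-rate effects of 0.10–0.40 for female sex, asthma,
mental-health history, comorbidity count and prior COVID-19
hospitalisation. The ratio-scale defaults mirror the headline effect sizes
reported for long COVID cohorts; the absolute comparator level (~16–21
visits/person-year) is in the reported range, while the exposed absolute
level runs higher than real-data reports because the generator's simple
covariate structure cannot reproduce the confounding that separates a
real cohort's adjusted ratios from its crude means. Empirical dispersion
and zero fractions are not published quantities; those defaults are free
parameters of the generator, not calibrated claims.

### What the oracle computes

`implied_effects()` turns the generator's parameters plus the simulated
covariate draw into the exact estimands the fitted models target:

* the first-part odds ratio from the hurdle probabilities;
* the conditional **deduplicated** rate ratio: same-day collapsing is a
  deterministic thinning of the counts, and its expectation has a closed
  form through the probability generating function of the truncated NB —
  for type share $s$ over a $D$-day window,
  $E[\text{distinct dates}] = D\,(1 - G_{\text{trunc}}(1 - s/D))$. The
  fitted count part targets this slightly attenuated ratio, not the raw
  event-rate ratio;
* the conditional total-cost ratio assembled from the same quantities and
  the unit-cost schedule;
* absolute group-by-period cell means and the implied DID contrast.

When given the matched-member table the oracle also accounts for **arm
composition**: because later-diagnosed people may serve as comparators
first, a synthetic comparator arm contains a few percent of
exposed-type generative histories (the real-data analogue is ~0.2%, but
the synthetic exposed fraction is much larger, so the overlap is too).
The oracle mixes the generative types within each arm exactly rather than
pretending the arms are pure.

### What the generator does not emulate

Coding-practice variation, vaccination dynamics, calendar epidemic waves,
joint covariate structure (covariates are drawn from marginal
distributions, group-specific for the clinical ones), cost-count
correlation beyond the shared count process, and informative censoring.
Passing tests therefore demonstrate that the estimators recover what the
generative model encodes — correct likelihoods, counting rules, matching
and standardisation — not that real EHR data meet those assumptions.

## Predictions, uncertainty, DID

Marginal standardisation averages counterfactual predictions over the
**full** member covariate distribution (not group-specific subsets), which
yields comparable adjusted means between arms. Uncertainty for predicted
means and the DID contrast uses a percentile **cluster bootstrap
resampling matched sets** (not rows), respecting the design; intervals are
reported only from 100+ replicates. The bootstrap is the package's
assumption — the CI method for predicted means is typically unstated in
applied reports — and delta-method intervals are deliberately out of
scope. Replicates that fail to converge are tolerated up to 5%, then the
bootstrap errors with a tally.

The DID is computed on the absolute predicted scale as the four-cell
contrast (both parts carry `group × period` interactions; the interaction
coefficients are reported alongside). Predictions standardise over
persons, not stacked person-periods, and the same covariate set is used in
both periods, with time-varying covariates (vaccine doses) frozen at their
index-date values. The common-trend check bins the pre-period, reports
per-bin visit rates per group with the between-group gap, and writes a
plot.

## Sensitivity suite

Stratified analyses refit both parts with a `group × stratum` interaction;
stratum-specific ORs and RRs are linear combinations of coefficients, and
the interaction is tested per part by a likelihood-ratio test with
`levels − 1` degrees of freedom (when the interaction family differs from
the main fit's, the main model is refitted under the interaction family so
the LRT compares nested models of one family). Restrictions implement the
usual robustness cohorts: prior GP consultation in the year before study
start, a positive test before index, and dropping each person's first
post-index GP visit. The descriptive table uses chi-square tests without
continuity correction (counts are large; conventional practice) and a
Welch t-test for age (configurable to pooled; the choice is rarely stated
in applied work).

## Problem sizes and runtime

The validation suite runs end-to-end recovery on cohorts of ~3,300 exposed
persons (≈20,000 analysis rows), Wald-coverage over 100 replicates of
2,000 rows, null calibration at ~700 exposed with 50 replicate interaction
tests, and bootstrap checks at a few hundred sets with 40–100 replicates.
These sizes are the package's own choice: large enough that Monte-Carlo
error sits well below the 3-standard-error test bands, small enough that
the whole suite is routinely re-runnable during development on a single
CPU.

## Known limitations

* Standard errors ignore matched-set clustering except where the cluster
  bootstrap is used; set-level random effects and GEE are out of scope.
* No zero-inflated (mixture) models: the two-part form assumes all zeros
  are structural "non-users of the window", which is also the generative
  form.
* Costs are not inflation-adjusted across years, outpatient visits have no
  per-specialty tariffs, and private-sector care is invisible by
  construction.
* Exact-age matching with finite comparator pools leaves some sets
  incomplete; the package keeps them, weighting the comparator arm
  accordingly.
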