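---
title: "Random versus systematic variation in hospital treatment rates: methods behind actbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random versus systematic variation in hospital treatment rates: methods behind actbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actbench)
```

## The problem

Provider profiling compares hospitals on a binary process-of-care indicator
— here, whether a patient with resected stage III colon cancer starts
adjuvant chemotherapy within 16 weeks of surgery. Hospital-specific rates
always vary; the analytic question is how much of that variation is
*systematic* (modifiable differences in practice or access) and how much is
binomial sampling noise, which is large when a hospital contributes a few
dozen cases over a study period. Benchmarks derived from the empirical rate
distribution — in particular the "pared-mean" Achievable Benchmarks of Care
(ABC) rate built from the top-ranked hospitals — inherit that noise: ranking
selects partly on luck, so under a pure-chance null the pared-mean benchmark
sits *above* the true common rate, and the implied shortfall is an artifact.
`actbench` implements the rate-variation decomposition, two benchmarking
methods, case-mix adjustment, and a calibrated synthetic-cohort generator so
all of it can be exercised and stress-tested end to end.

## Rate variation and the Monte Carlo null

The coefficient of variation of the hospital rates is `sd(r) / mean(r)` with
the sample (n − 1) standard deviation and every hospital counted once,
unweighted — each hospital is the unit of observation. Both choices are
conventions; volume-weighted alternatives answer a different (patient-level)
question.

The chance-only reference distribution is simulated under the null that
every hospital shares the pooled probability `p`: each iteration draws
`k_h ~ Binomial(n_h, p)` with the *actual* hospital denominators and
recomputes the CV. The mean of the simulated CVs is the expected CV; the
band is the empirical 2.5th–97.5th percentile interval, which is naturally
asymmetric (the CV distribution is right-skewed for small `n_h`). The
nonrandom component is the raw difference `observed − expected`, reported
even when negative, together with a flag for whether the observed CV lies
inside the null band.

Numerical details worth stating:

- Iterations where every simulated `k_h` is zero leave the CV undefined
  (mean 0); they are dropped from the distribution and counted
  (`n_degenerate`). This only matters for `p` near 0 or tiny cohorts.
- The CV is computed over all hospitals with at least one case by default.
  Low-volume exclusions in published *figures* are disclosure control, not
  analysis choices; `min_cases` is configurable where a sensitivity analysis
  wants them out.
- The per-hospital and pooled binomial intervals are Wilson score by
  default, with Wald as an option for comparability with reports that print
  symmetric intervals.

The simulation is validated two ways in the test suite: against exact
enumeration of the full outcome space on small hospital sets (within Monte
Carlo error), and by a coverage experiment — under the generator's exact
binomial null, the observed CV falls inside the null band in ~95% of
replicate cohorts (500 replicates of 200 iterations each; iteration counts
chosen to keep the experiment comfortably under a minute while leaving the
binomial standard error of the coverage estimate near one percentage
point). The coverage experiment zeroes the generator's covariate effects:
with them on, chance differences in case mix add real hospital-level
variance beyond the binomial null, which is a distinct (and separately
tested) phenomenon, not a miss of the null band.

## Case-mix adjustment

The outcome model is an ordinary maximum-likelihood logistic regression of
the treatment indicator on age group, sex, SES quintile, Charlson score,
length of stay (days, numeric), T stage, N stage, lymphovascular invasion
and histological grade. Reference levels are the youngest age group, female,
SES 1, Charlson 0, T3 (the modal stage), N1, well–moderate grade and no LVI.
"Unknown"-type levels are first-class categories except SES unknown, which
is so sparse (6 of 2801 in the emulated study) that rows are dropped with a
warning by default (`ses_unknown = "category"` keeps them). Complete
separation is detected before fitting and raised as an error naming the
offending covariate level.

Adjusted hospital rates use **indirect standardization**: the expected rate
`E_h` is the mean model-predicted probability over the hospital's own
patients, and the adjusted rate is `(O_h / E_h) × pooled`. The direction of
standardization was an open design choice; indirect is the provider-
profiling standard and is stable for small hospitals, whose own case mix is
too thin to support direct standardization. When every hospital has the
provincial case mix, `E_h` equals the pooled rate and adjusted collapses to
observed — a property the tests check exactly for the intercept-only model.

The bootstrap for the adjusted rates is parametric and fully specified,
because published descriptions of such procedures rarely are. Each
replicate:

1. redraws the coefficient vector from its asymptotic normal
   `N(beta_hat, Vcov)`;
2. recomputes each patient's model probability and rescales it by the
   hospital's observed/expected ratio (so the redrawn outcomes are centred
   on the hospital's standardized level, capped at 1);
3. redraws every outcome as a Bernoulli variable, and recomputes
   `(O*_h / E*_h) × pooled*`.

Per-hospital intervals are the 2.5/97.5 percentiles of the replicates. Step
2's rescaling is the package's interpretation: without it the draws are
centred on the pooled rate for every hospital and the "interval" is a null
band rather than a confidence interval for that hospital's adjusted rate.
1000 replicates is the default; the full matrix of draws is kept as an
attribute so downstream summaries (like the adjusted pared-mean benchmark)
can propagate uncertainty without refitting.

System-level factors (teaching status, comprehensive cancer centre, on-site
medical oncology) are assessed with one logistic model per factor (factor +
covariates) and **marginal standardization**: the average predicted
probability over the entire cohort with the factor forced to each level; the
adjusted relative risk is the ratio of those standardized rates, with
percentile intervals from coefficient redraws. This reproduces the paired
presentation of adjusted rates and adjusted RRs from one model and avoids
the convergence fragility of log-binomial fits. With no covariates the
factor model is saturated and the standardized rates equal the raw level
rates exactly — a collapse property the tests assert.

The multilevel model is a random-intercept logistic regression (hospital
intercepts, `lme4::glmer`, Laplace approximation). The intraclass
correlation on the latent scale is `sigma2_u / (sigma2_u + pi^2 / 3)`; it
and the CV nonrandom component must agree in sign, which is tested under
null and strong-effect generators.

## Benchmarks and shortfall

**Pared-mean (ABC).** Hospitals with fewer than 10 study cases are removed
first (the boundary case `n = 10` is retained), with an exact exclusion
report. Remaining hospitals are ranked by descending rate — ties broken by
larger volume (more evidence), then hospital id, making the selection
deterministic — and accumulated until the selected hospitals hold at least
10% of the population. Two interpretation choices are documented rather than
hidden:

- the 10% denominator is the *post-exclusion* (eligible) population; the
  published arithmetic is consistent with either convention, and using the
  eligible population keeps the benchmark self-contained;
- the stopping rule takes the first prefix reaching the threshold, so the
  selected share may slightly exceed 10%.

The benchmark rate is the pooled `k/n` over the selected hospitals; for the
adjusted variant (ranking on adjusted rates), it is the volume-weighted mean
of adjusted rates, with a percentile interval of the same weighted mean
across the bootstrap draws. Selection is verified against an independent
exhaustive prefix search on small instances.

**Criterion-based (CBB).** The benchmark is the marginal-standardized rate
at level 1 of a predefined optimal-access criterion (default: comprehensive
cancer centre), i.e. the rate the whole cohort would experience under the
criterion-meeting hospitals' practice, adjusted to the general case mix.

**Shortfall** is `(benchmark − actual) / benchmark × 100`, strictly
decreasing in the actual rate, zero at equality, negative when actual
exceeds benchmark, and undefined for a non-positive benchmark (an error).

The methodological centrepiece is testable end to end: under the pure-chance
null with study-like hospital volumes, the mean unadjusted pared-mean
benchmark exceeds the true rate (selection bias on binomial noise) and the
mean ABC shortfall is positive, while the mean CBB shortfall is centred on
zero. `abc_overestimation_experiment()` packages that contrast; the
acceptance tests run it at 200 replicates.

## The synthetic cohort generator

The generator emulates the structure the analysis assumes, with defaults
frozen to the emulated study's published aggregates: 72 hospitals, 2801
patients, marginal treatment probability 0.66, and the published covariate
marginals (where a table cell is range-suppressed, the midpoint consistent
with the column total is used). Treatment is drawn from
`logit(p) = b0 + x'beta + u_h` with:

- **Covariate effects**: by default an age gradient (0 to −3 log-odds from
  the youngest to the 80+ group) and a Charlson gradient (0, −0.4, −0.8) —
  direction per the emulated study's own prior finding that older, sicker
  patients receive less chemotherapy; magnitudes typical of adjuvant-therapy
  uptake in the elderly. All other effects default to zero.
- **Calibrated intercept**: `b0` solves `E[plogis(b0 + eta + u)] =
  base_rate` exactly, with the expectation taken over the exact discrete
  convolution of the configured covariate effect distributions and, when
  `hospital_sd > 0`, numerical integration over the random-intercept
  distribution; the logistic marginal mean is monotone in `b0`, so Brent
  root-finding converges to tolerance 1e−10.
- **Hospital volumes**: the true volume distribution is unpublished; the
  "study-like" profile draws lognormal weights (sigma 1.1) apportioned to
  the exact total by largest remainder, which reproduces the published
  aggregates (a realistic minority of hospitals under 10 cases, holding on
  the order of 150 patients). This profile is an assumption and is
  configurable (uniform, custom weights, forced small-hospital count).
- **Random-number policy**: one master seed with named substreams (sizes,
  flags, covariates, intercepts, outcomes), so changing one stage's
  configuration does not perturb the draws of another, and identical
  configurations give byte-identical cohort files.

Covariates are independent across patients and identical across hospitals
by default, because only marginals are published. One structured departure
is available: `case_mix_skew_covariate` gives each hospital an exponential
tilt of one covariate's level distribution (e.g. some hospitals see
systematically older patients), which is what makes case-mix adjustment
*matter* — under skew plus a real covariate effect, observed hospital rates
spread for reasons adjustment should (and, in the tests, does) remove, and
the adjusted pared-mean benchmark falls below the unadjusted one.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real registry data: covariate correlation structure
(stage with grade, age with comorbidity), time trends over an accrual
period, surgeon-level clustering within hospitals, non-random referral
(case-mix skew correlated with hospital quality), and informative
missingness in the "unknown" categories. With `case_mix_skew_sd > 0` the
intercept calibration is exact for the *base* marginals, so the realized
treatment fraction can drift a point or two from `base_rate` through the
nonlinearity; tests under skew therefore assert contrasts, not the marginal
rate.

## Problem sizes and tolerances in the test suite

Statistical assertions are run at sizes chosen so each check's Monte Carlo
error is small relative to the effect being asserted while the whole suite
stays interactive: enumeration-oracle comparisons at ≤ 3 hospitals within 3
Monte Carlo standard errors; CV-band coverage at 500 replicates × 200
iterations asserted in [0.92, 0.98]; logistic Wald coverage pooled over 200
replicate cohorts of full study size; random-intercept recovery at 60
replicates (variance within 3 empirical standard errors of truth);
selection-bias and benchmark contrasts at 200 and 20–30 replicates
respectively. Fixed seeds make every assertion deterministic.

## Known limitations

- Indirect standardization compares each hospital to its own expected rate;
  cross-hospital comparisons of adjusted rates are conventional but not
  strictly collapsible. Direct standardization is deliberately not offered
  for small hospitals.
- No empirical-Bayes shrinkage of hospital rates and no overdispersion
  multipliers on the funnel display; both are natural extensions the data
  structures already support (the rate table carries `n`, `k` and intervals).
- The pared-mean interval for the adjusted variant conditions on the
  selected set; selection uncertainty itself is not propagated (the
  overestimation experiment quantifies the induced bias instead).
- `glmer` variance estimates on 70-odd clusters carry non-trivial sampling
  error; the ICC is reported as a descriptive decomposition, not a test.
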