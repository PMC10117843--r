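---
title: "Methods: occupational cohort mortality with quantitative bias adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupational cohort mortality with quantitative bias adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occbias)
```

## Scope

`occbias` implements the analysis chain of an occupational-cohort mortality
reanalysis: external comparisons (SMRs against reference rate tables),
internal comparisons (conditional-likelihood rate ratios on explicit nested
case-control risk sets with lagged time-dependent exposure), and two
indirect adjustments for unmeasured confounding — the negative control
outcome (NCO) method on the rate-ratio side and the confounding-risk-ratio
(CRR) method with Monte Carlo sensitivity analysis on the SMR side. Because
cohort data of this kind are restricted, a synthetic multi-plant generator
with known confounding structure stands in for the study file; it is
first-class, tested code, not a fixture.

## Person-time and exposure

Follow-up runs from hire (not before 1942) to death or the study end date,
with deaths reported after the end date recoded to it by
`validate_and_recode()`. Person-time is split at every 5-year age-group
boundary (0–4, …, 85+), 5-year calendar-period boundary, and exposure
category transition; 5-year bands are the occupational-epidemiology default
and the convention of reference rate tables. Intervals are half-open
`[start, end)` at daily resolution, person-years are days/365.25; this
removes double counting at boundaries at the cost of calendar years not
being exactly 1.0 person-years (a leap year is 366/365.25).

Cumulative exposure at time *t* with lag *L* integrates intensity up to
*t − L*; the lag (default 10 years) encodes disease latency. Average
intensity (AIE) is defined here as lagged cumulative exposure divided by
lagged exposed duration; no authoritative formula exists for this metric,
so the ratio definition is a package decision, and whether the lag applies
to AIE is configurable (defaulting to the same lag as cumulative exposure).
Category intervals are right-closed above the origin — `[0, c1], (c1, c2],
…` — matching printed labels of the form "0–0.09" then ">0.09–0.64". Time
before a worker's first exposure, and never-exposed workers, fall in a
separate "unexposed" category (index 0), so lagged-zero time *after* first
exposure belongs to the lowest cut-point category instead.

Category transition dates are found analytically: within an exposure
segment both the lagged cumulative and the lagged AIE are ratios of linear
functions of time, so each cut-point crossing is a linear solve; candidate
dates are padded by ±1 day so each daily sub-interval has constant
category. A brute-force daily traversal in the test suite confirms
cell-level equality.

## SMRs

Expected deaths are the classical indirect standardization
E = Σ person-years × reference rate over strata (race × sex × age group ×
period). Confidence limits are exact Poisson (gamma-quantile) limits,
lower = qgamma(α/2, O)/E and upper = qgamma(1−α/2, O+1)/E, equivalent to
the chi-square/2 formulation; they reproduce published two-decimal CIs at
large O and remain valid for O < 10, where normal approximations fail. Note
these limits are conservative by construction: at E = 10 the true coverage
of the nominal 95% interval is 97.5%, not 95%.

No trend-test form is canonical for SMR tables; the package uses the Wald
p-value for the slope of a Poisson log-linear model
`O ~ offset(log E) + score`, with scores defaulting to category ranks
(mirroring quintile treatment) and exposure midpoints available via the
`scores` argument. The test suite checks its type-I error near 0.05 and a
permutation comparison on injected-trend data.

Any table cell whose observed count lies in (0, 10) is written as `"d.s."`
(data suppressed), mirroring the disclosure rule for small subcohort cells;
suppression is applied at report time only, internal values are retained.

## Risk sets and rate-ratio models

For each death from the index cause, the risk set contains every cohort
member under follow-up at the case's exact attained age (in days) whose
year of birth lies within a ±1-year caliper; the case's own later
appearance as a control in earlier sets is the incidence-density property.
All eligible controls are used by default; a seeded m:1 sampler exists for
large simulation studies. Two decedents with exactly equal death ages are
each cases in their own sets and not controls for one another. Sets with
zero eligible controls are flagged and excluded — their conditional
likelihood contribution is undefined. Race, sex and pay type enter as
covariates rather than matching factors. Time-dependent exposures are
evaluated for every member at the date they reach the case's event age,
with the configured lag.

With a single case per set, the exact conditional likelihood and the
Breslow/Cox partial likelihood coincide, so no tie approximation is needed;
the builder never generates multi-case sets. The log-likelihood is concave
and is maximised by Newton–Raphson from β = 0 with step-halving; the
variance is the inverse observed information. Convergence is declared at
gradient norm < 1e-8. Terms whose total within-set variation is below 1e-12
are reported as non-identifiable rather than fitted; a coefficient drifting
beyond |β| > 15 (monotone likelihood) marks the fit as separated, with
infinite variance, rather than crashing. The test suite checks the fitter
against matched-pair closed forms, brute-force maximization on small
instances, and `survival::clogit`.

The continuous dose-response model is the two-parameter log-linear-quadratic
RR(x) = exp(β₁x + β₂x²) on lagged cumulative exposure, fitted by the same
machinery; RR(0) = 1 by construction.

## Negative control outcome adjustment

An NCO is an outcome caused by the unmeasured confounder but — by
assumption — not by the exposure under study: COPD for smoking,
mesothelioma for asbestos. Under the *negative control condition* (no
exposure effect on the NCO) and the *equi-confounding assumption* (the
confounder biases NCO and outcome by the same multiplicative factor), the
confounding cancels in the ratio: β_adj = β_outcome − β_NCO, i.e.
RR_adj = RR_outcome / RR_NCO exactly. Two negative controls subtract both
coefficients; continuous models subtract coefficient-wise, so the adjusted
curve is the pointwise ratio of curves.

The adjusted variance is the sum of the component variances, treating the
two estimates as independent. The estimates share controls, so they are
positively correlated and the summed variance overstates the truth —
adjusted intervals are conservative. This is a deliberate, safe default;
estimates are consumed as (β, variance) pairs so the module applies equally
to fitted models and to published RRs with CIs (variance back-solved from
the CI half-width).

When equi-confounding fails, the method only partially adjusts and the
residual bias has a predictable direction (the test suite documents this
caveat: with a smoking–COPD effect weaker than the smoking–lung effect, the
adjusted RR remains biased upward).

## CRR adjustment and Monte Carlo sensitivity analysis

For external comparisons the indirect route uses only three scalars: the
confounder prevalence among exposed cohort members (p₁), in the reference
population (p₀), and the confounder–disease rate ratio (RR):

CRR = (p₁(RR − 1) + 1) / (p₀(RR − 1) + 1),  adjusted SMR = SMR / CRR.

A prevalence measured on an incomplete subset can be corrected by an
external anchor factor (`inflate_prevalence()`, clipped at 1 with a
warning). The Monte Carlo sensitivity analysis redraws (p₁, p₀, RR) from
priors — Beta for prevalences, moment-matched to a point estimate and 95%
range; log-normal for the RR, matched to a published CI; these are the
canonical choices in probabilistic bias analysis — recomputes the adjusted
SMR per draw, and reports the 2.5th/97.5th percentiles. The SMR's own
Poisson sampling error is included by default via a gamma draw with shape
O (toggleable), since interval widths otherwise understate uncertainty.
Invalid draws are rejected and redrawn, and every run is deterministic
given its seed.

One caveat when consuming published tables: reported adjusted values cannot
always be reconstructed from the printed unadjusted SMR and CRR alone —
rounding and unprinted intermediate steps intervene. The package always
recomputes adjusted SMRs from their inputs rather than matching such rows.

## The synthetic cohort: what it emulates, and what it does not

The generator emulates the *structure* of a large multi-plant production
cohort: 8 plants, hiring uniform over 1942–1980, follow-up through 2011,
plant-specific ever-smoking prevalences (0.53–0.78, mean ≈ 0.68),
smoking–lung and smoking–COPD hazard ratios of 19.1 (equal by default — the
equi-confounding structure the adjustment assumes), smoking–bladder 3.5,
and one plant (index 4) carrying extraneous asbestos exposure
(lung HR 3.0, mesothelioma HR 10, within the literature range for
shipyard-era asbestos). The exposure effect on lung cancer defaults to the
null, so the no-effect scenario is the generator's default and any apparent
exposure–response is pure confounding.

Mortality follows a yearly discrete-time competing-risks draw from
cause-specific hazards: smooth Gompertz-type baseline schedules (never-
smoker scale) by cause, sex and period, times the worker's smoking,
asbestos and exposure-category multipliers. Yearly steps match person-year
granularity and keep the generator dependency-free; the discretisation
error at the hazard magnitudes involved is below 1%. The COPD baseline uses
the same Gompertz slope and scale as lung cancer so that the negative
control's event-age profile matches the outcome's; with mismatched age
profiles, differential depletion of smokers at older ages breaks
equi-confounding at second order and biases the adjusted estimate.

Smoking–exposure confounding has two layers. The headline knob is `mixing`,
the probability that an ever-smoker holds an exposed job (default 0.75,
vs 0.55 for never-smokers). A single job-assignment knob, however, puts all
the confounding on the exposed/unexposed contrast and almost none on the
continuous ppm-year scale, which makes dose-response confounding invisible
next to estimator noise. The second layer, `intensity_smoking_gradient`,
therefore rank-couples smoking with the exposed career: intensity draws and
employment-duration draws keep their marginal distributions, but the higher
intensities and longer careers are routed preferentially to ever-smokers —
smokers hold the dustier, longer production jobs. With the default gradient,
P(smoker | cumulative exposure) rises across the whole exposure range.

Exposure intensities are log-normal with median 0.5 ppm and sdlog 1.1,
chosen so the exposed workers' lagged cumulative distribution matches the
emulated quintile cut points (roughly 16% above the 12.08 ppm-year top cut,
with a light far tail); employment durations are log-normal with median 6
years. Asbestos within the flagged plant is an individual Bernoulli draw
whose probability differs by exposure status (0.5 exposed vs 0.15
unexposed): an exposure-independent probability would inflate exposed and
unexposed lung rates equally and could not reproduce a plant-driven
confounding of the exposed-vs-unexposed RR.

The generator deliberately does **not** model hire-wave demographics, plant
closures, loss to follow-up, intra-plant rate heterogeneity beyond the
asbestos flag, or any attempt to match real death counts. Passing tests
therefore demonstrate that the estimators and adjustments behave as
advertised under known confounding — not that any real cohort satisfies
the negative control condition or equi-confounding, which are untestable
from data alone.

## Evaluation scenarios and problem sizes

The method-behaviour tests run desk-scale studies chosen to finish in
minutes while leaving clear Monte Carlo margins: 50 replicates of n = 5,000
workers for the equi-confounding null-recovery study (asbestos off, job
segregation at 0.80/0.45, 20:1 seeded control sampling, dose-response
curves compared by mean |log RR| over the data-supported 0–20 ppm-year
grid), 25 replicates of n = 4,000 for the asbestos-plant exclusion
comparison, 200 replicates for trend-test size, and 1,000 draws for exact
interval coverage. The full-scale cohort (~25,000 workers) is a
configuration change, not a code change.

## Known limitations

- The NCO variance treats outcome and NCO estimates as independent;
  intervals are conservative.
- The AIE definition (lagged cumulative / lagged exposed duration) is a
  stated convention, not an authoritative formula.
- The trend test is a Poisson Wald slope on rank scores; other score
  choices change p-values and are exposed through the `scores` argument.
- Exact Poisson limits over-cover (97.5% at E = 10 for nominal 95%).
- One exposure metric per person-time run; concurrent multi-agent
  person-time axes are out of scope.
- The generator's confounding structure is a modeling convenience with a
  documented joint distribution; it is not an estimate of any real cohort's
  smoking-exposure association.
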