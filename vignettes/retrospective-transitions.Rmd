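---
title: "Methods: retrospective transition cohorts and the progressive Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective transition cohorts and the progressive Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromsm)
```

## From one survey wave to a two-timepoint panel

The package targets surveys of adolescents (school grades 7–12) that ask,
for cigarettes and for electronic nicotine delivery systems (ENDS), whether
the respondent has ever used the product and at which school grade they
first used it (possible answers: "before entering elementary school" or
grades 1–12), plus past-30-day use frequency, sex, grade at first alcohol
use and paternal education.

The school year runs March through February and the survey is administered
in June, 4 months in. A reported initiation grade *below* the current grade
therefore implies ever-use already at the end of the previous grade — the
**baseline** — while initiation *at* the current grade occurred during the
4-month **follow-up**. Applying this to both products classifies every
respondent into one of four mutually exclusive ever-use states at both
timepoints:

| code | state |
|------|-------|
| 1 | never use |
| 2 | cigarette only |
| 3 | ENDS only |
| 4 | cigarette and ENDS |

Ever-use states can only be entered, so the chain is progressive: the only
instantaneous moves are 1→2, 1→3, 1→4, 2→4 and 3→4, and state 4 is
absorbing. A panel cell like (1, 4) is still observable — it is the
simultaneous-initiation pathway, reached either by the direct 1→4 jump
(both products within one sitting, or within a window too short to
resolve) or by passing through 2 or 3 inside the interval.

**Cohort construction choices.** Complete-case exclusions are applied
sequentially — ever-cigarette users missing the cigarette initiation grade,
then remaining ever-ENDS users missing the ENDS grade, then records missing
paternal education — so each record is counted under exactly one reason and
the per-reason counts sum to the total dropped. Ever alcohol use *at
baseline* uses the same previous-grade-or-earlier rule as the products. A
past-30-day frequency reported by a respondent whose ever flag is false is
logically impossible; we warn and force the current-use flag false rather
than trust either answer. A numeric initiation grade above the current
grade is an error (inconsistent recall), never silently truncated. The
follow-up interval is a configurable constant `interval_months = 4`.

## The model and its likelihood

Transitions follow a time-homogeneous continuous-time Markov chain with
intensity matrix $Q$ whose five free entries $q_{rs}$ are rates per month;
rows sum to zero and all other off-diagonal entries are structural zeros.
Covariates $z$ act log-linearly with transition-specific coefficients,

$$q_{rs}(z) = \exp(\alpha_{rs} + \beta_{rs}^\top z),$$

which keeps every rate positive for any finite parameter value, so the
optimisation is unconstrained. (A shared-coefficient mode,
`shared_covariates = TRUE`, constrains $\beta_{rs} \equiv \beta$.) Dummy
coding: female = 1, ever alcohol = 1, paternal-education reference is
college-or-higher; numeric design columns (baseline grade) are centered, so
the default reporting profile `"means"` is the cohort mean of the design
columns.

Exact transition times are never observed — only the states at the two
timepoints — so each record contributes a panel term and the weighted
log-likelihood is

$$\ell = \sum_i w_i \log \big[\exp\!\big(Q(z_i)\, t_i\big)\big]_{s_i^{(0)},\, s_i^{(1)}}.$$

Records sharing a covariate pattern and interval are aggregated first; with
categorical covariates the cost per likelihood evaluation is a handful of
$4\times4$ exponentials however large the cohort.

**Saturated-model identity.** With a single common interval and no
covariates the five free parameters map one-to-one onto the five free cells
of the transition-proportion matrix (rows 1–3 of $P$), so the ML-fitted
$P(4)$ *equals* the empirical row proportions, and the fitted $Q$ equals
the algebraic inversion `invert_single_interval()` of those proportions.
This identity is the module's primary oracle: it is checked to $10^{-4}$ on
a 59 796-record fixture in the test suite, and means that for the null
model the optimiser is verifying a closed-form answer, not discovering one.

## Numerical choices

* **Transition probabilities.** The exported general route `tpm()` is a
  scaling-and-squaring Padé (order 13) matrix exponential. The progressive
  chain also admits an exact spectral solution, `tpm_closed()`, with
  `expm1`-based limiting forms when exit rates coincide; the two agree
  within $10^{-10}$ over 1000 random intensity matrices in the tests (and
  against an independent implementation, `Matrix::expm`). Because the
  numeric-gradient quasi-Newton fit evaluates $P(t)$ on the order of $10^5$
  times per covariate model, the likelihood's inner loop uses the analytic
  solution; it is exact for this structure, and the equivalence of the two
  routes is continuously enforced by the oracle tests rather than assumed.
* **Optimiser.** BFGS on the negative log-likelihood (relative tolerance
  $10^{-12}$, up to 500 iterations), started from the single-interval
  inversion of the pooled empirical proportions with zero covariate
  effects. On failure, up to 5 restarts jittered with seeded Gaussian noise
  (sd 0.3); the seed is recorded in the fit. Non-convergence is an explicit
  error, never a silent result. The covariance is the inverse observed
  information from a numerical Hessian at the optimum.
* **Degenerate data.** A transition with zero directly observed cells would
  push its intercept to $-\infty$; instead the intercept is frozen at
  $\log(10^{-12})$ with a warning and excluded from the optimisation and
  covariance. Absurd rates probed by the line search (> $10^6$/month) are
  rejected with a large penalty rather than allowed to overflow.
* **Time units.** Months throughout, with $t = 4$ as the panel interval.
  The likelihood is invariant to a joint rescaling of $t$ and the rates
  (months to years shifts every $\alpha$ by exactly $\log 12$); this
  invariance is tested rather than a unit being guessed where none is
  forced.

## Reported quantities

* **TIR** $= q_{rs}(z)/q_{uv}(z)$. Its log is a linear combination of
  parameters, so the CI is the delta method on the log scale,
  $\exp(\widehat{\log \mathrm{TIR}} \pm 1.96\,\mathrm{SE})$ — closed form,
  no simulation. With transition-specific $\beta$ the covariate profile
  does not cancel and is always reported with the estimate.
* **TP matrix** at $t$ and a profile $z$: point estimate
  $\exp(Q(\hat\theta; z) t)$; CIs by parametric simulation — $B = 1000$
  draws from $N(\hat\theta, \hat V)$, $P$ recomputed per draw, percentile
  intervals per cell, seed recorded. Percentile rather than Wald intervals
  keep the bounds inside $[0, 1]$ near the boundary. Structural zeros are
  reported as exact 0 with no interval.
* **Model ladder.** `compare_models()` adds sex, baseline grade, ever
  alcohol and paternal education one at a time to the null model and
  tabulates $-2\ell$, AIC and the likelihood-ratio test against the
  previous model; a failed member is flagged and the ladder continues.
* **Prevalence by transition group.** Movers are cross-classified into
  current cigarette-only / ENDS-only / dual use; unweighted proportions get
  Wilson score intervals, and the weighted mode uses the effective sample
  size $(\sum w)^2 / \sum w^2$ in the same interval. Combined categories
  pool counts and recompute one interval (never summing interval bounds);
  since the categories are disjoint over one denominator, the combined
  point estimate equals the sum of the component proportions.

## What the synthetic generator emulates — and what it does not

`generator_config()` encodes the study conditions the analysis assumes: a
progressive chain started in state 1 at the beginning of grade 1, run by
competing exponential clocks with subject-specific log-linear intensities;
initiation times binned to school grades for the questionnaire; current-use
frequency bands drawn conditional on ever-use at survey time; and MCAR
missingness per field. Defaults: desk-scale baseline rates
$q_{12} = 0.004$, $q_{13} = q_{14} = 0.0006$, $q_{24} = q_{34} = 0.025$
per month (of the order implied by observed adolescent transition tables);
48% female; uniform grades 7–12; paternal-education marginals 53.7 / 25.1 /
21.2%; an alcohol-initiation hazard of 0.0045/month (chosen so roughly a
third of subjects are ever-drinkers by a mid-cohort baseline); emission
bands in which just under half of ever-users are current users. Covariate
marginals are independent by default because the joint distribution of the
emulated survey is not published; effects enter through
`covariate_effects` when a simulation needs them. A configurable pre-school
hazard window (default off) generates "before entering elementary school"
answers.

The generator deliberately does **not** emulate: recall bias (reported
grades are exact bins of the true times), school drop-out, complex-survey
weighting and clustering, cessation or switching (states are ever-use by
construction), or correlation between covariates. Passing tests therefore
demonstrate that the estimator recovers the generating process under the
model's own assumptions — a necessary internal-validity check — not that
those assumptions hold in any real survey.

## Validation design and problem sizes

The test suite works at three scales, chosen to keep each check sharp:

* exact arithmetic on a 59 796-record fixture reproducing a published
  transition cross-table (and a 60 040-record variant reproducing a
  published exclusion pattern), where the saturated identity makes the
  right answers known in closed form;
* distributional checks at $n = 50\,000$: simulator-versus-analytic
  transition proportions within 3 Monte-Carlo standard errors, and a
  20-replicate recovery study in which the generating intensity ratio
  $q_{34}/q_{12} = 6.8$ must be covered by the fitted 95% TIR interval in
  at least 18 replicates, with log-intensity RMSE shrinking from
  $n = 10\,000$ to $n = 50\,000$;
* small-$n$ property checks (Wilks behaviour of null covariates, AIC
  detection of a real effect, weight-expansion and time-unit invariances)
  at $n$ between 5000 and 30 000 with 5–10 replicates each.

## Known limitations

* Time-homogeneous intensities: initiation hazards that rise through
  adolescence are averaged over each subject's exposure window. The panel
  interval is short (4 months), which limits, but does not remove, the
  impact on fitted rates.
* The retrospective panel inherits recall's failure modes; the builder
  surfaces inconsistent recall as errors but cannot correct it.
* Per-record weights are supported in the likelihood and prevalence
  tables, but full complex-survey variance estimation (strata, clusters,
  replicate weights) is out of scope, so weighted intervals are
  approximations via the effective sample size.
* With transition-specific coefficients and many covariates the full model
  has 30 parameters; at small $n$ with rare transitions (state 3 is
  typically ~1% of a cohort) some cells can be too sparse for the normal
  approximation behind the Wald and simulation intervals.
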