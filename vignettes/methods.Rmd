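---
title: "Methods: cohort design, categorical-treatment TMLE, and the synthetic claims generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort design, categorical-treatment TMLE, and the synthetic claims generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific and numerical choices behind
`claimstmle`: the cohort-design algebra, the targeted minimum loss-based
estimator (TMLE) for a six-level categorical treatment, the super learner
used for both nuisance fits, and the synthetic-claims data-generating
process (DGP) that stands in for administrative claims data that cannot be
redistributed.

# Study design encoded by the cohort builder

The target of inference is the 3-year risk of incident type 2 diabetes and
of all-cause death had every member of a new-user antipsychotic monotherapy
cohort initiated a given drug, contrasted against the active comparator
aripiprazole.  The cohort builder applies, in fixed order:

1. **Monotherapy episode.** At least two fills of the same index drug
   totalling at least 31 days supply inside a 90-day window; the index date
   is the date of the first fill.  Windows are half-open `[t, t + 90)` and
   anchored at fill dates: since the index date is defined as a fill date,
   a qualifying window must start at some fill, and the brute-force oracle
   in the test suite scans exactly those anchors.  Days supply is summed
   without stockpiling adjustment — the criterion is a simple total.  When
   a person qualifies for two drugs, the earlier index date wins; a
   same-day tie is dropped with a logged reason, because any drug
   attribution would be arbitrary.
2. **Relatively-new user.** No fill of a *different* antipsychotic in the
   183-day pre-period.  Fills of the index drug itself are allowed and
   their summed days supply becomes the pre-period exposure confounder.
   The pre-period is the open interval `(index − 183, index)`: a record
   exactly 183 days before the index date lies outside it.  All pre-period
   measurement (washout, exclusions, confounders) uses this same window.
3. **Enrollment continuity.** Month-granular coverage (a calendar month is
   covered or not) over the pre-period through the index month and over the
   six post-index months; a person who dies in the post-period passes if
   covered up to the month before the month of death.
4. **Condition exclusions.** Any pre-period diagnosis in the configured
   exclusion sets (type 2 diabetes, dyslipidemia, hypertension,
   cardiovascular disease, antidiabetic-managed conditions such as
   polycystic ovary syndrome) removes the person.  Type 1 diabetes is
   deliberately *not* exclusionary; it feeds the chronic-conditions
   health-status indicator.  Unknown claim codes warn and do not exclude.
5. **Follow-up.** From the index date to the earliest of the 3-year cap
   (1095 days), the administrative end of study (2013-12-31), the 65th
   birthday, the last covered day before a coverage gap, or death.  The
   stored end day is the last day under observation (inclusive).  On
   same-day ties the recorded reason follows death, then the 3-year cap,
   then end of study, then turning 65, then coverage loss — the
   end-of-study > turning-65 > coverage-loss order is the design's stated
   hierarchy, and death is placed first because a death observed on a
   covered day is an outcome, not a censoring.  Months uncovered *because*
   of death (at or after the death month) are not treated as coverage
   loss.  Censoring only terminates outcome lookup; no censoring weights
   are used, and death is not modelled as a competing risk for diabetes.

Calendar arithmetic is integer day indices with day 0 = 2008-07-01 (the
accrual origin), half-open intervals everywhere, and calendar months
indexed from January 2008.  "6 months" is operationalised as 183 days and
"3 years" as 1095 days; the design phrases are calendar-language only, so
these fixed-day conventions are declared once and used consistently by the
code, the generator and the oracles.

# Outcome ascertainment

Type 2 diabetes is called when any of three branches fires inside
follow-up: (a) an inpatient claim with the diabetes code in primary
position; (b) two outpatient claims (any position) within any 365-day
window; (c) one outpatient claim plus an oral-antidiabetic fill.  The
evidence day is the earliest completion day of any branch.  Branch (c)'s
claim–fill temporal link is not pinned down by the design language; the
package requires the fill within ±365 days of the claim, mirroring branch
(b)'s 12-month window, and flags this as a configuration-level convention.
Two outpatient claims on the same day count as two claims.  Death is a
recorded death date inside follow-up.

# The estimator

For the cohort `O_i = (W_i, A_i, Y_i)` with `A` the six-level index drug
and `Y` a binary 3-year outcome, the target parameters are
`psi_a = E_W[ Qbar(a, W) ]` with `Qbar(a, w) = P(Y = 1 | A = a, W = w)`.

**Initial fits.** Both nuisances are estimated by a super learner:
cross-validated stacking over a learner library, with simplex weights
minimising held-out negative log-likelihood.  The outcome task enters the
treatment as a categorical covariate and predicts with the treatment column
set to each drug in turn; the propensity task is multinomial with folds
stratified by drug so the rare haloperidol arm (~6%) appears in every
training split.

**Targeting.** One fluctuation parameter per treatment level:
`logit Qbar*_eps(a, W) = logit Qbar0(a, W) + eps_a / g(a | W)`, with
`eps_a` the MLE over the rows with `A = a`.  A single targeting step
exactly solves the per-level EIC score equation, so the per-arm mean of
`D*_a = 1{A=a}/g(a|W) (Y − Qbar*(A, W)) + Qbar*(a, W) − psi_a` is
numerically zero (the suite asserts `|mean| ≤ 1e-6`).  A per-level
fluctuation was chosen over one joint multinomial fluctuation because it
solves each arm's score exactly in one step and keeps the update local to
the arm whose propensity it corrects; the exact update equations are a
design choice of this package.

**Inference.** `SE(Delta_a) = sd(D*_a − D*_c)/sqrt(n)`; 95% Wald intervals
with multiplier 1.96; no multiplicity adjustment across the five pairwise
comparisons.  Relative differences are `100 × Delta / r_c` with `r_c` the
comparator's *unadjusted* outcome rate, reported to one decimal.

**Subgroups and sensitivity.** Subgroup estimates average the fitted
per-person differences `Qbar*(a, W) − Qbar*(c, W)` within each subgroup of
a partition — no refitting — so size-weighted subgroup estimates rebuild
the overall estimate as an algebraic identity (tested to 1e-12).  Subgroup
standard errors use the subgroup-restricted EIC contrast with the subgroup
treated as fixed; whether the overall fit's estimation error should
propagate into subgroup intervals is left open by the reporting convention
we mirror, and the fixed-fit choice is documented so users who prefer
refitting can do so.  The sensitivity subcohort (age < 45 and zero
pre-period index-drug exposure — people with less opportunity for latent
disease and less prescriber-visible history, hence less vulnerable to
confounding by indication) is averaged the same way from the full-cohort
fit.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `g_bound` | 0.005 | probability | positivity protection for the ~6% haloperidol arm; truncation + renormalisation iterated until every entry respects the bound |
| `k` (CV folds) | 10 | folds | conventional bias/variance compromise for stacking |
| Q-clip | 1e-4 | probability | keeps `logit Qbar0` finite for the fluctuation |
| CV-loss clip | 1e-6 | probability | bounds the log-likelihood loss |
| CI multiplier | 1.96 | — | nominal 95% Wald interval, no multiplicity adjustment |
| `min_n` (subgroups) | 50 | persons | rows from smaller subgroups carry a `low_n` flag instead of being dropped |

## Numerical choices

* The fluctuation MLE is found by bracketed root-finding on the monotone
  score (`uniroot`, tol 1e-12) followed by Newton polish; degenerate arms
  (all events or none) cap `eps` at ±20, where the submodel is flat.
* Super-learner weights solve `min -mean log(P w) + 1e-8 ||w||²` over the
  simplex by the mixture-EM update from a uniform start (the objective is a
  convex mixture likelihood), with a vertex guard so the stacked ensemble
  never loses to its best member.  The tiny L2 penalty makes the solution
  unique under ties; its minimiser splits the weight of duplicated
  learners equally, and the suite asserts exactly that.
* Fold assignment deals shuffled stratum members cyclically with one
  running pointer, so fold sizes differ by at most one globally and within
  every stratum.
* Learners that fail on any fold are dropped with a warning (risk = +Inf)
  rather than aborting; unseen factor levels at prediction map to the
  reference level with a warning.

# The synthetic-claims generator

The generator emulates the *structure* of the study's claims extracts: a
person table (birth date, sex, race/ethnicity, state, payer, SMI
diagnosis, death date), pharmacy fills with days supply and drug-class
flags, diagnosis claims with setting and position, and month-granular
enrollment.  Covariates are drawn from configurable marginals; treatment
follows a multinomial-logit model in the covariate features; outcomes are
logistic with additive per-drug effects (optionally with feature-by-drug
interactions for effect-modification studies).  Because assignment and
outcomes are generated from the same closed-form models, true
counterfactual risks are computable — exactly, by enumerating the joint
support when every confounder is discrete, otherwise by Monte Carlo with a
reported simulation SE.

Default marginals follow the published cohort description: 52% male, 65%
White, 55% schizophrenia, 74% dual coverage, 55% California residents, 18%
metabolic testing, 81% with pre-period index-drug exposure (mean 109 days,
s.d. 70 among the exposed), ages 18–64, index years 2008–2013.  Assignment
intercepts are calibrated so drug shares sit near the observed
26.5/20/18/17/11.5/6% split, with schizophrenia channelled toward
haloperidol and away from aripiprazole and cardiometabolic risk factors
channelled toward the metabolically safer drugs; outcome intercepts are
calibrated to ~9.3% 3-year diabetes incidence and ~5% mortality, with
per-drug logit effects sized so haloperidol and olanzapine carry ≈ −2 pp
diabetes risk and every drug carries +1 to +2 pp mortality risk against
aripiprazole.  The nine utilization counts default to independent
negative-binomial draws: their dependence structure is not described in
the cohort literature we mirror, so independence is the declared default
and the confounder list is fully configurable.

Two deliberate idealisations matter for interpreting test results:

* **Early-event emission.** Outcome evidence (diabetes claim patterns,
  death dates) is emitted inside each person's guaranteed-observable
  window, so the latent outcome equals the claims-ascertained outcome for
  every cohort member.  Real claims misclassify and right-truncate
  outcomes; passing recovery tests therefore demonstrates correctness of
  the estimator and pipeline, not robustness to outcome misclassification.
* **Random thinning.** The filter-violation flags (single-fill episodes,
  other-antipsychotic use, exclusionary diagnoses, coverage gaps) are
  drawn independently of covariates, treatment and outcomes, so attrition
  is exercised without inducing selection bias and the generator's true
  risks remain valid for the analytic cohort.  Real attrition is of course
  differential; the cohort builder does not know or use this independence.

Other omissions: no geographic or temporal autocorrelation, no cost
fields, no realistic ICD-9/NDC vocabularies (small stylized label sets are
used, configurable via `default_code_config()`), no prescriber effects,
no medication adherence.

# Problem sizes in the test suite

The suite runs at sizes chosen to make its statistical assertions sharp
while keeping a full run around three minutes: parameter recovery runs the
complete claims pipeline at n = 5000 with Monte-Carlo truth at 2e5 draws
(simulation SE ≈ 1e-4, negligible against EIC SEs ≈ 5e-3); double
robustness uses 200 replicates at n = 5000 on the all-discrete simulation
configuration (enumerated truth; Monte-Carlo error of the bias estimate
≈ 0.01 pp against the 0.5 pp bound); interval coverage uses 500 replicates
at n = 2000 under a null DGP with a ±2-binomial-SE acceptance band; the
design-rule oracles run 1000 random fill/claim sets against exhaustive
scans.  Repeated-fit studies use single-learner libraries (the super
learner reduces to the learner itself) so the replicate loops measure the
estimator, not stacking overhead.

# Known limitations

* Cross-fitted (CV-)TMLE, longitudinal TMLE and survival-time parameters
  are out of scope; outcomes are fixed-horizon binary indicators.
* The simplex solver's EM iteration converges slowly in nearly-flat
  directions; the vertex guard bounds the consequence (never worse than
  the best single learner), which is the property the theory needs.
* Enumeration-based truth is limited to configurations whose joint
  confounder support fits in memory (default cap 1e5 cells); the default
  configuration uses Monte-Carlo truth.
* With very rare arms and a tight truncation bound, clever-covariate
  values up to 200 make the fluctuation step noticeably noisy in small
  samples — visible in the fixed-point test's tolerance, which is set at a
  few per-arm EIC standard errors.
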