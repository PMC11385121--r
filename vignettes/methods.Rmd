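---
title: "Reanalysing a two-arm vasopressor trial: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reanalysing a two-arm vasopressor trial: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialhte)
```

## The problem

The SOAP II trial randomized 1679 patients with shock to first-line
dopamine (n = 858) or norepinephrine (n = 821) and reported a neutral
primary result for 28-day mortality (unadjusted OR 1.17, 95% CI 0.97–1.42)
alongside clearly more arrhythmias under dopamine. `trialhte` implements a
modern reanalysis toolkit for this kind of two-arm ICU trial: generalized
pairwise comparisons (win ratio) over endpoint hierarchies, Bayesian
outcome models under a neutral prior with probabilistic summaries,
Bayes-factor-gated interaction reporting, risk-based heterogeneity of
treatment effect (HTE) over recalibrated severity-score quartiles, and
effect-based HTE through an S-learner with a counterfactual recommendation
rule.

The original patient-level data are not deposited. The package therefore
ships a synthetic cohort generator calibrated to the trial's published
baseline table, so every stage of the pipeline can be exercised — and,
more importantly, *tested against known ground truth*. All analyses in
`analysis/` run on that synthetic cohort; none of their posterior numbers
are estimates of the original trial's numbers, though the qualitative
pattern (fewer wins for dopamine, high probability of harm on the
composite endpoint) reproduces because the generator is calibrated to the
same margins.

## Endpoints

* `death28` — all-cause 28-day mortality (the trial's primary endpoint).
* `composite` — death, new renal replacement therapy (RRT), or new
  arrhythmia.
* `daficu28` — days alive and free of ICU at 28 days: 0 for patients who
  die by day 28, otherwise `28 - icu_los` clamped to `[0, 28]`. The
  survivor formula is our reading of "days alive and free of ICU"; ICU
  stays may exceed 28 days, hence the clamp.

Variables with at most 1% missingness are imputed with the observed median
(continuous) or most common level (categorical); a tie between modes is
broken lexicographically and recorded — the convention is arbitrary, but a
deterministic convention beats a random one.

## Win ratio

For a hierarchy of endpoints, every treatment–control patient pair within
a stratum is compared level by level: at a binary level the patient
without the event wins; at a continuous level the favoured direction wins
when the absolute difference exceeds the tie margin; otherwise the pair
passes to the next level, and a pair undecided after the last level is a
tie (no early stopping). The stratified win ratio pools strata by summed
wins: WR = Σ treatment wins / Σ control wins, so WR < 1 means fewer wins
for the treatment (dopamine) arm. Alternative stratum weightings exist; we
expose the tallies so any of them can be derived, but the headline number
is the unweighted "total wins" reading.

Two hierarchies are preset. The first is death → new RRT → new arrhythmia.
The second is death → ICU length of stay, where **lower ICU length of stay
wins** among pairs tied on death. The direction deserves emphasis because
it is a genuine design choice: a shorter stay is the favourable outcome,
which makes this hierarchy conceptually close to days alive and free of
ICU. The tie margin defaults to 0 days. Two deaths tie at the first level
regardless of timing — mortality is a 28-day binary here, not a
time-to-event.

Inference: the default is a patient-level bootstrap (2000 resamples,
resampling within arm-by-stratum cells, fixed seed) with a percentile CI
and a two-sided p-value from percentile inversion of the bootstrap log-WR
distribution, because no analytic variance is canonical for the pooled
statistic. A closed-form alternative based on the two-sample U-statistic
variance of the win and loss proportions (delta method on log WR) is
provided for cross-checking; on the default synthetic cohort the two
agree closely (stage 3 of `analysis/` prints both).

The tally engine counts wins by sorted rank queries and recurses on tied
groups, which is what makes bootstrap inference affordable; its
correctness is not taken on faith but pinned to exhaustive pair
enumeration through `compare_pair()` on hundreds of random small cohorts
in the test suite. A positive tie margin at a non-terminal level makes
ties non-transitive, so such groups fall back to dense pair enumeration.

## Bayesian outcome models

Models are logistic (binary endpoints) or Gaussian (`daficu28`) with a
treatment indicator, optional factor (shock group, risk quartile), optional
treatment-by-factor interaction, and optional covariates. Priors:

* treatment coefficient: **Normal(0, 0.355)** on the log-OR scale — a
  neutral prior under which odds ratios beyond ~2 are implausible; for the
  Gaussian days-alive model, Normal(0, 5 days) (the log-OR prior's scale
  has no meaning in days, so it is not reused);
* treatment-by-covariate interactions: Normal(0, 1) on the log-OR scale
  (Normal(0, 5 days) Gaussian) — effect modification beyond e-fold odds
  changes is rarely credible, and an excessively diffuse interaction prior
  would make the interaction Bayes factor insensitive by construction
  (Bartlett's paradox);
* other coefficients: weakly informative Normal(0, 2.5) on standardized
  predictors (scaled by the outcome SD in the Gaussian family); intercept
  likewise; Gaussian residual scale: half-Student-t(3) scaled to the
  outcome SD. All are overridable per fit.

**Sampling.** Posteriors are drawn by an independence Metropolis sampler:
the mode and curvature come from an optimizer (Laplace approximation) and
a multivariate Student-t(6) proposal centred there, inflated by 1.2, is
accepted or rejected against the exact unnormalized posterior, in 4 chains
of 1000 kept iterations by default. At trial sample sizes these GLM
posteriors are near-Gaussian, so acceptance rates sit around 0.6–0.9 and
chains mix almost independently; correctness is still checked per fit by
split R-hat (any parameter above 1.01 flags the fit invalid, and
downstream code refuses flagged fits unless forced) and effective sample
sizes via Geyer's initial-positive-sequence estimator. The sampler is
validated in the tests against deterministic oracles: 1-D quadrature for
an intercept-only logistic posterior and the conjugate closed form for a
Gaussian model with fixed residual scale. With zero observations the
treatment posterior reproduces the prior.

**Marginal effects (g-computation).** For each posterior draw, every
cohort patient is predicted under both counterfactual arms and the
averages are differenced (risk difference, mean difference) or converted
to a marginal odds ratio. Standardization is over the whole cohort by
default — whether to standardize per stratum is genuinely open; per-level
summaries pass `subgroup =` to restrict the standardization population.
Summaries report the posterior median, the 95% highest-density interval
(narrowest-window algorithm over sorted draws), the probability of
direction Pd = max(P(θ>0), P(θ<0)) (floored at 0.5 for the degenerate
all-zero case), and the mass inside the region of practical equivalence
(ROPE): ±0.01 absolute risk for binary endpoints, ±1 day for `daficu28`.
Verdicts are a pure function of (Pd, ROPE mass): Pd > 0.95 with ROPE mass
< 0.05 is "strong evidence of effect", Pd > 0.90 is "suggestive of
effect", anything else "no clear effect".

**Bayes factors.** Marginal likelihoods come from iterative (Meng–Wong)
bridge sampling between the posterior sample and a moment-matched Gaussian
proposal, with the proposal fitted on one half of the draws and evaluated
on the other to avoid reuse bias; four repetitions with fresh proposal
samples give a Monte-Carlo standard error. The estimator is validated
against quadrature on a normal-mean toy. The interaction Bayes factor
compares the models with and without the treatment-by-factor block, and
gates reporting: per-level summaries are produced only when BF > 10,
otherwise only the no-interaction model is reported — the
conditional-reporting rule applied to all three endpoints for shock groups
and risk quartiles alike.

## Risk-based HTE

Because the original APACHE II probability equation cannot be evaluated
without admission-diagnosis data, the score is recalibrated as a
first-level customization: a maximum-likelihood logistic regression of
28-day death on the raw score, refit in the cohort. Discrimination is
reported as the Mann–Whitney AUC (exhaustive pairwise, ties one half) and
calibration as a decile table of mean predicted versus observed risk; the
simultaneous-band "calibration belt" is deliberately out of scope, the
decile table being the plain-text substitute. Quartiles of predicted risk
are cut on the pooled cohort (randomization makes the score
treatment-independent) with the bracket convention `[lowest, q1] (q1, q2]
(q2, q3] (q3, highest]`. Because the score is integer-valued, predictions
tie heavily and quartile sizes deviate from n/4 by the tied mass — labels
follow the boundaries, which keeps them invariant under strictly monotone
transforms of predicted risk; fully tied predictions are an error, not a
silent single stratum. Each endpoint then gets the BF-gated interaction
analysis with risk quartile as the factor; quartile is modelled as a
4-level factor only (no residual continuous-score adjustment inside
quartiles).

## Effect-based HTE (S-learner)

The cohort is split 60/40 within each arm (test size =
`floor(0.4 * n_arm)` per arm, 671 of 1679 at the published sizes; the
rounding rule matters only at the margin and is fixed per arm for
reproducibility). On the training set a single logistic model of the
composite endpoint is fitted with age, shock group, cardiomyopathy and
total SOFA, each interacting with arm — exactly those four covariates, no
more. For every test patient and every posterior draw the model predicts
the composite risk under both counterfactual arms; the per-draw difference
(dopamine minus norepinephrine) is the individualized treatment-effect
(ITE) posterior. "Probability of benefit" for an arm is the draw-wise sign
frequency — P(difference > 0) favours norepinephrine — and an arm is
recommended when that probability exceeds 0.90; otherwise no
recommendation. Coverage counts recommendations over the *whole* test set,
including patients excluded for factor levels unseen in training (they
count as "none": coverage is a property of the test set, not of the
predictable subset). If coverage reaches 25%, outcomes are assessed by a
logistic model of the composite on recommendation group × received arm,
reported as g-computation risk differences of receiving dopamine within
each recommendation group. Recommendations are outcome-blind on the test
set by construction, and the tests verify both this anti-leak property and
the sign symmetry of the ITE under negated treatment coding.

## The synthetic cohort generator

The generator emulates the published baseline table: arm sizes 858/821;
shock mix septic 62.2%, cardiogenic 16.7%, hypovolemic 15.7%, anaphylactic
0.4%, other 5.1% (collapsed to septic/cardiogenic/other for analysis); age
~ Normal(65, 14.5) rounded and clipped; APACHE II as a rounded
gamma(shape 5.0, scale 4.46), matched to the printed median 21 and IQR
(15, 28); SOFA ~ Normal(8.8, 3.8) rounded and clipped to [0, 24], linked
to APACHE II by a Gaussian copula with correlation 0.52 (Spearman ≈ 0.5 —
the true correlation is unreported; this is a configurable guess, not an
assertion about the trial); the SOFA total is then split over the six
organ components (each capped at 4) with random weights centred on the
printed component means; cardiomyopathy 50.5%, mechanical ventilation
71.2%, baseline RRT 7.4%, female 43%.

Outcomes: 28-day death follows a logistic model in shock group (offsets
0 / +0.35 / −0.7 for septic / cardiogenic / other — cardiogenic shock the
most lethal, non-septic non-cardiogenic the least), APACHE II (+0.07 per
point) and SOFA (+0.12 per point), with intercept −0.0882 and treatment
log-OR 0.195 calibrated by large-sample Monte Carlo so the marginal
per-arm mortality is 52.4% / 48.5% as printed. Arrhythmia and new RRT are
covariate-free logits whose intercepts and treatment effects are exact
arithmetic from the printed counts (24% vs 12%; 7% vs 10%). Survivor ICU
length of stay is a discretized gamma(1.4, scale 7.7), calibrated so mean
days alive and free of ICU lands at about 8–9 days per arm as printed;
patients who die get a shorter stay draw that the days-alive derivation
ignores. Outcomes are conditionally independent given covariates and arm
(the trial reports no joint model); the only deterministic coupling is
death ⇒ zero days alive and free of ICU. One master seed derives a
deterministic sub-seed per generation block, so identical (config, seed)
is byte-identical output.

What the generator does *not* emulate: vasopressor doses and titration,
time-varying hemodynamics, informative censoring, correlated adverse
events, site effects. Passing tests on this cohort therefore demonstrate
that the *machinery* is correct and calibrated — recovery of known
effects, honest null behaviour, gate specificity — not that any specific
posterior from the original data would be reproduced.

Named scenarios freeze the study conditions used by the tests:
`config_null()` (no treatment effect anywhere), `config_uniform_harm()`
(one log-OR bump of 0.2407 on death, arrhythmia and RRT, calibrated so the
true marginal composite risk difference is 0.06), and
`config_strong_interaction()` (dopamine harm confined to cardiogenic
shock). The interaction magnitude defaults to 2.0 on the log-OR scale
following a power analysis at the trial's size: an interaction confined to
the ~17% cardiogenic stratum has an expected standard error near 0.35 at
n = 1679, so a Δβ of 1.0 (expected z ≈ 2.9) is genuinely undetectable in a
large fraction of replicates by any method — the tests verify that Δβ =
1.0 is detected reliably at about twelve times the trial size, and use
Δβ = 2.0 for gate-sensitivity checks at the trial's own size.

## Numerical choices and degenerate inputs

* Mode ties in imputation: lexicographic, logged.
* HDI: narrowest window over sorted draws; a single draw yields a
  degenerate interval.
* Bootstrap log-WR with a zero win count in a resample: 0.5 continuity
  offset for that resample only; the point estimate itself is reported as
  upper-unbounded when the control arm never wins.
* A stratum with an empty arm is skipped with a warning and excluded from
  pooling; no stratum at all is an error.
* Rank-deficient design matrices error out rather than sampling a
  non-identified posterior; constant severity scores and fully tied risk
  predictions are errors with the tied mass named.
* Bridge sampling adds a tiny ridge to the proposal covariance and errors
  on non-convergence rather than returning a silent number.

## Problem sizes in the test suite

The suite exercises the full stack at sizes chosen to keep a complete run
in the tens of minutes on one core: oracle equivalence of the win-ratio
engine on 500 random cohorts of up to 30 patients; treatment-effect
recovery over 50 replicate cohorts at the published size (n = 1679);
gate behaviour over 10 + 10 replicates at n = 1679; S-learner recovery of
a uniform 0.06 composite harm at n = 20 000; null calibration of the
bootstrap win-ratio test over 200 cohorts of n = 400 (rejection rate at
α = 0.05 must fall in [0.02, 0.09]) and of recommendation restraint over
10 null replicates (mean coverage below 15%).

## Limitations

The Bayesian engine covers the GLM term structure this pipeline needs —
it is not a general regression package (no random effects, no survival
models, no formula interface). The win ratio here is the binary/continuous
hierarchy form, not the time-to-event form, and win odds / net benefit are
derivable from the tallies but not headline outputs. The asymptotic WR
variance ignores between-stratum weighting subtleties that the bootstrap
handles naturally. Multiple imputation is out of scope (the 1% rule makes
single imputation immaterial). And the synthetic cohort, however carefully
calibrated to the printed margins, cannot stand in for the original
patient-level data where joint distributions matter.
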