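# trialhte

Reanalysis toolkit for two-arm randomized trials in critical care, built
around the dopamine-versus-norepinephrine shock trial (SOAP II: 1679
patients, 858 dopamine / 821 norepinephrine, neutral primary result for
28-day mortality with unadjusted OR 1.17, 95% CI 0.97–1.42). The package
implements, as reusable tested code, the modern reanalysis battery for
such a trial:

* **Stratified win ratio** — generalized pairwise comparisons over ordered
  endpoint hierarchies (death → renal replacement → arrhythmia; death →
  ICU length of stay), all treatment–control pairs within each shock
  stratum, pooled by summed wins:
  WR = Σ wins_T / Σ wins_C, with WR < 1 meaning fewer wins for dopamine.
  Patient-level bootstrap CI/p by default, U-statistic asymptotics for
  cross-checking.
* **Bayesian outcome models** — logistic / Gaussian GLMs under a neutral
  Normal(0, 0.355) prior on the treatment log-odds ratio, sampled by an
  independence Metropolis algorithm with a Laplace multivariate-t
  proposal; marginal (g-computation) risk differences and odds ratios;
  posterior median, 95% highest-density interval, probability of
  direction Pd, and mass in the region of practical equivalence (ROPE:
  ±0.01 risk, ±1 day for days alive and free of ICU). Verdicts are a pure
  function of (Pd, ROPE mass): Pd > 0.95 with ROPE < 0.05 is strong
  evidence, Pd > 0.90 suggestive.
* **Bayes-factor interaction gate** — bridge-sampling marginal
  likelihoods; treatment-by-factor interactions are reported per level
  only when BF > 10, otherwise the no-interaction model alone.
* **Risk-based HTE** — APACHE II recalibrated by logistic regression on
  in-cohort mortality, Mann–Whitney AUC and decile calibration, quartiles
  of predicted risk, BF-gated quartile-by-treatment analysis.
* **Effect-based HTE** — an S-learner: one outcome model with age, shock
  group, cardiomyopathy and SOFA all interacting with arm, trained on a
  60% split; counterfactual predictions give per-patient treatment-effect
  posteriors; an arm is recommended when its probability of benefit
  exceeds 0.90; recommendation-concordance outcomes are assessed when
  coverage reaches 25%.
* **Synthetic cohort generator** — the patient-level trial data are not
  deposited, so the generator emulates the published baseline table
  (shock mix, APACHE II median 21 IQR 15–28, SOFA 8.8 ± 3.8, per-arm
  mortality 52%/48%, arrhythmia 24%/12%, new RRT 7%/10%) with
  configurable treatment effects and interactions, so every stage is
  testable against known ground truth.

See `vignettes/methods.Rmd` for the models, priors, numerical choices and
their rationale.

## Worked example

```r
library(trialhte)

gen <- generate_cohort(cohort_config(), seed = 5)    # published-margin cohort
ds  <- derive_endpoints(gen$cohort)

compute_win_ratio(ds, hierarchy_death_rrt_arrhythmia(),
                  strata = "shock_group", ci = "bootstrap",
                  n_boot = 2000, seed = 7)
#> Win ratio (treatment = dopamine): 0.800
#>   95% CI (bootstrap): 0.679 - 0.942; two-sided p = 0.01299
#>   pooled wins T/C/ties: 99568 / 124464 / 97730 over 3 strata

fit <- bglm_fit(ds, bglm_spec("death28", "bernoulli_logit",
                              factor = "shock_group"), seed = 2)
summarize_draws(marginal_effect(fit, "risk_difference"))
#> median 0.04031 [95% HDI -0.002729, 0.08666], Pd = 0.958, ROPE(-0.01, 0.01) mass = 0.085
```

Read: on this synthetic cohort dopamine accrues 20% fewer pairwise wins
than norepinephrine on the death/RRT/arrhythmia hierarchy (WR 0.80,
p ≈ 0.01), and the adjusted posterior puts a 4-point median increase in
28-day mortality on dopamine with probability of harm 0.96 — only 8.5% of
the posterior lies within ±1% risk. The numbers are properties of the
calibrated generator, not estimates of the original trial's posteriors,
but the qualitative pattern matches because the generator is calibrated
to the same published margins.

The full analysis sequence lives in `analysis/01_simulate_cohort.R`
through `analysis/07_full_report.R` — thin numbered drivers over the
package that write their tables and JSON artifacts under `results/`. Run
them in order from the repository root after installing the package.

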