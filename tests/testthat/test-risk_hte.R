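mk_risk_cohort <- function(apache, death, arm = NULL) {
  n <- length(apache)
  if (is.null(arm)) arm <- rep(c("dopamine", "norepinephrine"), length.out = n)
  derive_endpoints(as_trial_cohort(tibble::tibble(
    id = sprintf("r%03d", seq_len(n)), arm = arm, shock_type = "septic",
    age = 60, sex = "m", apache2 = apache, sofa_total = 8,
    cardiomyopathy = FALSE, mech_vent = FALSE, baseline_rrt = FALSE,
    death28 = death, new_rrt = FALSE, new_arrhythmia = FALSE, icu_los = 5)))
}

test_that("score recalibration is a deterministic monotone logistic fit", {
  ds <- mk_risk_cohort(c(10, 20, 30, 40), c(FALSE, FALSE, TRUE, TRUE))
  m <- suppressWarnings(customize_score(ds))  # toy is perfectly separated
  expect_gt(m$slope, 0)
  p <- m$predict_risk(c(10, 20, 30, 40))
  expect_true(all(diff(p) > 0))
  expect_equal(evaluate_risk_model(m, ds)$auc, 1)  # Mann-Whitney enumeration
  expect_error(customize_score(mk_risk_cohort(rep(20, 10),
                                              rep(c(TRUE, FALSE), 5))),
               "constant")
})

test_that("recalibration recovers the generator's severity slope", {
  cfg <- cohort_config(
    n_per_arm = c(dopamine = 3000, norepinephrine = 3000),
    death_model = list(beta_sofa = 0, beta_trt = 0,
                       shock_offset = c(other = 0, septic = 0, cardiogenic = 0)))
  ds <- generate_cohort(cfg, seed = 31)$cohort
  m <- customize_score(ds)
  se <- sqrt(diag(vcov(glm(death28 ~ apache2, data = ds,
                           family = binomial()))))[2]
  expect_lt(abs(m$slope - 0.07), 1.96 * se)
})

test_that("pairwise AUC equals exhaustive enumeration, ties counted one half", {
  expect_equal(auc_mann_whitney(c(0.9, 0.6, 0.4, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE)), 1)
  for (s in 1:10) {
    set.seed(400 + s)
    n <- sample(10:100, 1)
    pred <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # heavy ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(y) == 0 || sum(!y) == 0) next
    expect_equal(auc_mann_whitney(pred, y), brute_force_auc(pred, y))
  }
  set.seed(41)
  noise <- runif(5000)
  y <- sample(c(TRUE, FALSE), 5000, replace = TRUE)
  expect_lt(abs(auc_mann_whitney(noise, y) - 0.5), 0.03)
})

test_that("well-calibrated predictions track observed event fractions by decile", {
  cfg <- cohort_config(n_per_arm = c(dopamine = 5000, norepinephrine = 5000),
                       death_model = list(beta_sofa = 0, beta_trt = 0,
                                          shock_offset = c(other = 0, septic = 0,
                                                           cardiogenic = 0)))
  ds <- generate_cohort(cfg, seed = 32)$cohort
  m <- customize_score(ds)
  cal <- evaluate_risk_model(m, ds)$calibration
  expect_true(all(abs(cal$mean_predicted - cal$observed) < 0.04))
})

test_that("risk quartiles follow the bracket convention and split evenly without ties", {
  ds <- mk_risk_cohort(seq(10, 45, 5), rep(c(FALSE, TRUE), 4))
  m <- customize_score(ds)
  strat <- stratify_by_risk(ds, m)
  expect_equal(as.integer(table(strat$labels)), rep(2L, 4))
  expect_match(strat$intervals[1], "^\\[")
  expect_match(strat$intervals[2], "^\\(")
  # all-equal predictions are degenerate
  flat <- mk_risk_cohort(c(10, 20, 30, 40), c(FALSE, FALSE, TRUE, TRUE))
  const_model <- structure(list(predict_risk = function(a) rep(0.5, length(a))),
                           class = "risk_model")
  expect_error(stratify_by_risk(flat, const_model), "degenerate")
})

test_that("quartile labels are invariant to strictly monotone transforms of risk", {
  ds <- toy_cohort(200, seed = 42)
  m <- customize_score(ds)
  m_mono <- structure(list(predict_risk = function(a)
    plogis(3 * qlogis(m$predict_risk(a)) + 1)), class = "risk_model")
  expect_identical(stratify_by_risk(ds, m)$labels,
                   stratify_by_risk(ds, m_mono)$labels)
})

test_that("the interaction gate controls the report shape deterministically", {
  ds <- derive_endpoints(generate_cohort(cohort_config(), seed = 43)$cohort)
  m <- customize_score(ds)
  strat <- stratify_by_risk(ds, m)
  rep_ <- risk_hte_analysis(ds, strat, endpoints = c("death28", "daficu28"),
                            chains = 2, iter = 700, warmup = 100, seed = 44)
  for (e in rep_$endpoints) {
    if (is.na(e$bf) || e$bf <= 10) expect_null(e$per_quartile)
    else expect_named(e$per_quartile, c("Q1", "Q2", "Q3", "Q4"))
  }
})

test_that("a single-quartile stratification collapses to the plain arm model", {
  ds <- toy_cohort(120, seed = 45)
  strat <- structure(list(
    boundaries = numeric(3),
    labels = factor(rep("Q1", nrow(ds))),
    intervals = "[0,1]", predicted = rep(0.5, nrow(ds))),
    class = "risk_stratification")
  rep_ <- risk_hte_analysis(ds, strat, endpoints = "death28",
                            chains = 2, iter = 700, warmup = 100, seed = 46)
  e <- rep_$endpoints$death28
  expect_true(is.na(e$bf))
  expect_null(e$per_quartile)
  expect_s3_class(e$overall$difference, "posterior_summary")
})
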