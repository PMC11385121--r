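test_that("the split is arm-stratified, disjoint, exhaustive and reproducible", {
  ds <- toy_cohort(40, seed = 50)
  ds$arm <- rep(c("dopamine", "norepinephrine"), each = 20)
  ds <- derive_endpoints(as_trial_cohort(tibble::as_tibble(ds)))
  # 10 per arm at 0.6: floor(0.4*10) = 4 test, 6 train per arm
  small <- ds[c(1:10, 21:30), ]
  sp <- split_train_test(small, 0.6, seed = 51)
  expect_equal(as.integer(table(sp$train$arm)), c(6L, 6L))
  expect_equal(as.integer(table(sp$test$arm)), c(4L, 4L))
  expect_equal(nrow(sp$test), 8)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), small$id)
  sp2 <- split_train_test(small, 0.6, seed = 51)
  expect_identical(sp$test$id, sp2$test$id)
  expect_error(split_train_test(small, 1.2), "train_frac")
})

test_that("the published cohort sizes give a test set of 671 at the default fraction", {
  ds <- generate_cohort(cohort_config(), seed = 52)$cohort
  sp <- split_train_test(ds, 0.60, seed = 53)
  expect_equal(nrow(sp$test), floor(0.4 * 858) + floor(0.4 * 821))  # 343 + 328
  expect_equal(nrow(sp$test), 671L)
})

test_that("all-zero treatment coefficients give identically zero effect estimates", {
  ds <- toy_cohort(30, seed = 54)
  spec <- bglm_spec("composite", "bernoulli_logit", factor = "shock_group",
                    interaction = TRUE, covariates = c("age", "sofa_total"),
                    covariate_interaction = TRUE)
  design <- trialhte:::bglm_design(ds, spec)
  pn <- colnames(trialhte:::bglm_build_X(design, ds))
  K <- 50
  set.seed(55)
  dr <- matrix(rnorm(K * length(pn), 0, 0.3), K)
  colnames(dr) <- pn
  dr[, grepl("^trt", pn)] <- 0  # treatment main effect and every interaction
  fit <- trialhte:::bglm_fit_from_draws(ds, spec, dr)
  model <- structure(list(fit = fit, outcome = "composite"), class = "s_learner")
  ites <- predict_counterfactuals(model, ds)
  expect_true(all(attr(ites, "draws") == 0))
  expect_true(all(ites$median == 0))
})

test_that("a hand-set single-covariate model reproduces the closed-form effect", {
  ds <- toy_cohort(12, seed = 56)
  spec <- bglm_spec("composite", "bernoulli_logit", covariates = "sofa_total",
                    covariate_interaction = TRUE)
  design <- trialhte:::bglm_design(ds, spec)
  co <- c(`(Intercept)` = -1, trt = 0.5, sofa_total = 0.3, `trt:sofa_total` = -0.2)
  fit <- trialhte:::bglm_fit_from_draws(ds, spec, matrix(co, 1))
  model <- structure(list(fit = fit, outcome = "composite"), class = "s_learner")
  ites <- predict_counterfactuals(model, ds)
  z <- (ds$sofa_total - design$cov_center["sofa_total"]) /
    design$cov_scale["sofa_total"]
  expected <- plogis(-1 + 0.5 + (0.3 - 0.2) * z) - plogis(-1 + 0.3 * z)
  expect_equal(as.vector(attr(ites, "draws")), expected)
  # identical patients get identical posteriors
  two <- ds[c(1, 1), ]; two$id <- c("p1", "p2")
  ites2 <- predict_counterfactuals(model, two)
  expect_equal(ites2$median[1], ites2$median[2])
})

test_that("negating the treatment coding flips effect signs and swaps benefit fields", {
  ds <- toy_cohort(25, seed = 57)
  spec <- bglm_spec("composite", "bernoulli_logit", covariates = "age",
                    covariate_interaction = TRUE)
  set.seed(58)
  K <- 100
  dr <- cbind(rnorm(K, -0.5, 0.3), rnorm(K, 0.3, 0.3),
              rnorm(K, 0.2, 0.3), rnorm(K, 0.1, 0.3))
  fit <- trialhte:::bglm_fit_from_draws(ds, spec, dr)
  # under the negated coding trt' = 1 - trt the equivalent parameters are
  # a' = a + b, b' = -b (and likewise for the interaction pair)
  dr_neg <- cbind(dr[, 1] + dr[, 2], -dr[, 2], dr[, 3] + dr[, 4], -dr[, 4])
  fit_neg <- trialhte:::bglm_fit_from_draws(ds, spec, dr_neg)
  m <- structure(list(fit = fit, outcome = "composite"), class = "s_learner")
  m_neg <- structure(list(fit = fit_neg, outcome = "composite"), class = "s_learner")
  a <- predict_counterfactuals(m, ds)
  b <- predict_counterfactuals(m_neg, ds)
  expect_equal(attr(a, "draws"), -attr(b, "draws"))
  expect_equal(a$p_benefit_norepi, b$p_benefit_dopa)
  expect_equal(a$p_benefit_dopa, b$p_benefit_norepi)
})

test_that("recommendations follow the threshold rule and coverage is monotone", {
  ites <- tibble::tibble(
    id = sprintf("p%02d", 1:10),
    excluded = c(rep(FALSE, 9), TRUE),
    median = 0, hdi_low = 0, hdi_high = 0,
    p_benefit_norepi = c(0.99, 0.95, 0.91, 0.80, 0.50, 0.20, 0.05, 0.03, 0.01, NA),
    p_benefit_dopa = c(0.01, 0.03, 0.05, 0.15, 0.45, 0.75, 0.93, 0.95, 0.97, NA))
  r <- make_recommendations(ites, threshold = 0.90)
  expect_equal(r$n_norepinephrine, 3)
  expect_equal(r$n_dopamine, 3)
  expect_equal(r$n_none, 4)          # includes the excluded patient
  expect_equal(r$coverage, 0.6)
  expect_true(r$assessment_eligible)
  cov_at <- vapply(c(0.6, 0.7, 0.8, 0.9, 0.96),
                   function(th) make_recommendations(ites, th)$coverage, 0)
  expect_true(all(diff(cov_at) <= 0))
  diffuse <- ites
  diffuse$p_benefit_norepi <- pmin(ites$p_benefit_norepi, 0.7)
  diffuse$p_benefit_dopa <- pmin(ites$p_benefit_dopa, 0.7)
  r0 <- make_recommendations(diffuse, threshold = 0.90)
  expect_equal(r0$coverage, 0)
  expect_false(r0$assessment_eligible)
  expect_error(assess_recommendations(toy_cohort(10, 1), r0), "below the")
})

test_that("recommendations are blind to test-set outcomes", {
  ds <- derive_endpoints(generate_cohort(
    cohort_config(n_per_arm = c(dopamine = 300, norepinephrine = 300)),
    seed = 59)$cohort)
  sp <- split_train_test(ds, 0.6, seed = 60)
  model <- fit_s_learner(sp$train, chains = 2, iter = 700, warmup = 100, seed = 61)
  test_perm <- sp$test
  set.seed(62)
  test_perm$composite <- sample(test_perm$composite)
  a <- predict_counterfactuals(model, sp$test)
  b <- predict_counterfactuals(model, test_perm)
  expect_equal(attr(a, "draws"), attr(b, "draws"))
  expect_identical(make_recommendations(a)$recommendation,
                   make_recommendations(b)$recommendation)
})

test_that("concordance assessment collapses cleanly when one group dominates", {
  ds <- derive_endpoints(generate_cohort(
    cohort_config(n_per_arm = c(dopamine = 200, norepinephrine = 200)),
    seed = 63)$cohort)
  recs <- structure(list(
    recommendation = tibble::tibble(id = ds$id, recommendation = "norepinephrine"),
    threshold = 0.9, coverage = 1, n_norepinephrine = nrow(ds),
    n_dopamine = 0, n_none = 0, n_excluded = 0, assessment_eligible = TRUE),
    class = "recommendation_set")
  a <- assess_recommendations(ds, recs, chains = 2, iter = 700, warmup = 100,
                              seed = 64)
  expect_named(a$contrasts, "norepinephrine")
  expect_s3_class(a$contrasts$norepinephrine, "posterior_summary")
})
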