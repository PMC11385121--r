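empty_cohort <- function() {
  tibble::tibble(arm = character(0), death28 = numeric(0))
}

test_that("with zero observations the treatment posterior equals the neutral prior", {
  sp <- bglm_spec("death28", "bernoulli_logit")
  fit <- bglm_fit(empty_cohort(), sp, chains = 2, iter = 2000, warmup = 100,
                  seed = 1)
  b <- fit$draws[, "trt"]
  expect_lt(abs(mean(b)), 0.03)
  expect_lt(abs(sd(b) - 0.355), 0.02)
  s <- summarize_draws(b, rope = c(-0.01, 0.01))
  expect_lt(s$pd, 0.55)
})

test_that("an intercept-only Bernoulli posterior matches 1-D quadrature", {
  # oracle: numerically integrate the exact posterior of the event
  # probability under the same Normal prior on the logit
  # the treatment coefficient is pinned by a near-zero prior so the fit is
  # intercept-only in effect; the intercept keeps its Normal(0, 2.5) prior
  n_ev <- 7; n <- 20
  df <- tibble::tibble(arm = rep(c("dopamine", "norepinephrine"), 10),
                       y = rep(c(TRUE, FALSE), c(n_ev, n - n_ev)))
  post_kernel <- function(a) {
    vapply(a, function(ai)
      exp(n_ev * ai - n * log1p(exp(ai)) + dnorm(ai, 0, 2.5, log = TRUE)),
      0)
  }
  z <- integrate(post_kernel, -10, 10)$value
  oracle_mean_p <- integrate(function(a) plogis(a) * post_kernel(a) / z,
                             -10, 10)$value
  fit <- bglm_fit(df, bglm_spec("y", "bernoulli_logit",
                                priors = list(treatment = c(0, 1e-6))),
                  chains = 2, iter = 3000, warmup = 100, seed = 3)
  p_draws <- plogis(fit$draws[, "(Intercept)"])
  expect_lt(abs(mean(p_draws) - oracle_mean_p), 0.01)
})

test_that("injected coefficients reproduce closed-form marginal effects exactly", {
  ds <- toy_cohort(20, seed = 2)
  sp <- bglm_spec("death28", "bernoulli_logit")
  a <- -0.4; b <- 0.7
  fit <- trialhte:::bglm_fit_from_draws(ds, sp, matrix(c(a, b), 1))
  rd <- marginal_effect(fit, "risk_difference")
  expect_equal(rd, plogis(a + b) - plogis(a))
  or <- marginal_effect(fit, "odds_ratio")
  expect_equal(or, exp(b))
})

test_that("posterior summaries: degenerate, normal and uniform draw sets", {
  s <- summarize_draws(rep(0.5, 1000), rope = c(-0.01, 0.01))
  expect_equal(s$median, 0.5)
  expect_equal(c(s$hdi_low, s$hdi_high), c(0.5, 0.5))
  expect_equal(s$pd, 1)
  expect_equal(s$rope_mass, 0)

  set.seed(4)
  z <- rnorm(1e5)
  h <- hdi_interval(z, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.03)
  expect_lt(abs(h[["upper"]] - 1.96), 0.03)
  # HDI and equal-tailed interval agree for symmetric unimodal draws
  q <- quantile(z, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(h[["lower"]] - q[1]), 0.03)
  expect_lt(abs(h[["upper"]] - q[2]), 0.03)

  set.seed(5)
  u <- runif(5000, -0.01, 0.01)
  expect_equal(summarize_draws(u, rope = c(-0.01, 0.01))$rope_mass, 1)
})

test_that("large-sample posterior median recovers the generator's treatment effect", {
  cfg <- cohort_config(
    n_per_arm = c(dopamine = 10000, norepinephrine = 10000),
    death_model = list(intercept = 0, beta_apache = 0, beta_sofa = 0,
                       shock_offset = c(other = 0, septic = 0, cardiogenic = 0),
                       beta_trt = 0.405))
  ds <- generate_cohort(cfg, seed = 6)$cohort
  fit <- bglm_fit(ds, bglm_spec("death28", "bernoulli_logit"),
                  chains = 2, iter = 1000, warmup = 100, seed = 7)
  expect_true(fit$valid)
  expect_lt(abs(median(fit$draws[, "trt"]) - 0.405), 0.05)
})

test_that("a Gaussian conjugate posterior with fixed residual scale is exact", {
  set.seed(8)
  y <- rnorm(40, 2, 1)
  df <- tibble::tibble(arm = rep(c("dopamine", "norepinephrine"), 20), y = y)
  # intercept-only in effect: treatment prior collapsed to zero
  fit <- bglm_fit(df, bglm_spec("y", "gaussian",
                                priors = list(treatment = c(0, 1e-6),
                                              intercept = c(0, 2),
                                              sigma_fixed = 1)),
                  chains = 2, iter = 3000, warmup = 100, seed = 9)
  # conjugate normal-normal: posterior precision = n + 1/tau^2
  tau <- 2
  post_var <- 1 / (length(y) + 1 / tau^2)
  post_mean <- post_var * sum(y)
  a <- fit$draws[, "(Intercept)"]
  expect_lt(abs(mean(a) - post_mean), 3 * sqrt(post_var / length(a)) + 0.01)
  expect_lt(abs(sd(a) - sqrt(post_var)), 0.02)
})

test_that("bridge sampling matches the analytic marginal likelihood of a normal-mean model", {
  # y_i ~ N(mu, 1), mu ~ N(0, tau^2): everything closed-form
  set.seed(10)
  y <- rnorm(30, 0.8, 1)
  # the marginal likelihood is evaluated by high-resolution quadrature of
  # likelihood x prior (a deterministic, independent oracle)
  quad_logml <- function(tau) {
    f <- function(mu) vapply(mu, function(m)
      exp(sum(dnorm(y, m, 1, log = TRUE)) + dnorm(m, 0, tau, log = TRUE)), 0)
    log(integrate(f, -10, 10, rel.tol = 1e-10)$value)
  }
  draws_post <- function(tau, k) {
    n <- length(y)
    v <- 1 / (n + 1 / tau^2)
    matrix(rnorm(k, v * sum(y), sqrt(v)), ncol = 1)
  }
  logpost <- function(tau) function(th) {
    mu <- th[, 1]
    vapply(mu, function(m) sum(dnorm(y, m, 1, log = TRUE)), 0) +
      dnorm(mu, 0, tau, log = TRUE)
  }
  set.seed(11)
  ml1 <- bridge_logml(draws_post(1, 4000), logpost(1), reps = 4, seed = 1)
  ml2 <- bridge_logml(draws_post(0.25, 4000), logpost(0.25), reps = 4, seed = 2)
  bf_bridge <- exp(ml1$logml - ml2$logml)
  bf_true <- exp(quad_logml(1) - quad_logml(0.25))
  expect_lt(abs(log(bf_bridge / bf_true)), log(1.05))
})

test_that("identical models give a Bayes factor of 1 within Monte-Carlo error", {
  ds <- toy_cohort(300, seed = 12)
  sp <- bglm_spec("death28", "bernoulli_logit", factor = "shock_group")
  bf <- bayes_factor(ds, sp, sp, chains = 2, iter = 1000, warmup = 100, seed = 13)
  expect_lt(abs(log(bf$bf)), 0.1)
  expect_false(bf$supports_interaction)
})

test_that("specs differing beyond the interaction block are rejected", {
  sp1 <- bglm_spec("death28", "bernoulli_logit", factor = "shock_group",
                   interaction = TRUE)
  sp2 <- bglm_spec("composite", "bernoulli_logit", factor = "shock_group")
  expect_error(bayes_factor(toy_cohort(20, 1), sp1, sp2), "interaction block")
})

test_that("relabeling the factor reference leaves risk-difference draws unchanged", {
  ds <- toy_cohort(40, seed = 14)
  ds$grp <- ifelse(ds$shock_group == "septic", "s", "ns")
  sp <- bglm_spec("death28", "bernoulli_logit", factor = "grp",
                  interaction = TRUE)
  # equivalent parameterizations under the two reference levels
  set.seed(15)
  K <- 200
  dr <- cbind(rnorm(K, -0.3, 0.2), rnorm(K, 0.4, 0.2),
              rnorm(K, 0.2, 0.2), rnorm(K, -0.5, 0.2))
  fit_ref_ns <- trialhte:::bglm_fit_from_draws(ds, sp, dr)
  # reference "s": intercept' = a + f, f' = -f, trt' = b + i, i' = -i
  ds2 <- ds
  ds2$grp <- factor(ds2$grp, levels = c("s", "ns"))
  dr2 <- cbind(dr[, 1] + dr[, 3], dr[, 2] + dr[, 4], -dr[, 3], -dr[, 4])
  fit_ref_s <- trialhte:::bglm_fit_from_draws(ds2, sp, dr2)
  expect_equal(marginal_effect(fit_ref_ns, "risk_difference"),
               marginal_effect(fit_ref_s, "risk_difference"))
  expect_equal(marginal_effect(fit_ref_ns, "risk_difference", subgroup = "s"),
               marginal_effect(fit_ref_s, "risk_difference", subgroup = "s"))
})

test_that("verdict strings are a pure function of direction and ROPE mass", {
  expect_identical(effect_verdict(0.99, 0.01), "strong evidence of effect")
  expect_identical(effect_verdict(0.96, 0.20), "suggestive of effect")
  expect_identical(effect_verdict(0.92, 0.01), "suggestive of effect")
  expect_identical(effect_verdict(0.85, 0.01), "no clear effect")
  expect_identical(effect_verdict(0.5, 1), "no clear effect")
  expect_error(effect_verdict(0.3, 0))
})

test_that("invalid or degenerate fits are flagged and guarded", {
  df <- toy_cohort(30, seed = 16)
  df$death28 <- FALSE
  df$composite <- df$death28 | df$new_rrt | df$new_arrhythmia
  expect_warning(fit <- bglm_fit(df, bglm_spec("death28", "bernoulli_logit"),
                                 chains = 2, iter = 300, warmup = 50, seed = 1),
                 "no outcome variation")
  expect_true(fit$degenerate)
  # a manually invalidated fit is refused downstream unless forced
  fit$valid <- FALSE
  expect_error(marginal_effect(fit, "risk_difference"), "flagged invalid")
  expect_silent(marginal_effect(fit, "risk_difference", force = TRUE))
})

test_that("rank-deficient designs error instead of sampling silently", {
  ds <- toy_cohort(30, seed = 17)
  ds$dup <- ds$age
  sp <- bglm_spec("death28", "bernoulli_logit", covariates = c("age", "dup"))
  expect_error(bglm_fit(ds, sp), "rank deficient")
})

test_that("a unit interaction is overwhelmingly detectable at twelve times the trial size", {
  cfg <- cohort_config(
    n_per_arm = c(dopamine = 10000, norepinephrine = 10000),
    death_model = list(interaction = c(other = 0, septic = 0, cardiogenic = 1.0)))
  ds <- derive_endpoints(generate_cohort(cfg, seed = 18)$cohort)
  sp1 <- bglm_spec("death28", "bernoulli_logit", factor = "shock_group",
                   interaction = TRUE)
  sp0 <- bglm_spec("death28", "bernoulli_logit", factor = "shock_group",
                   interaction = FALSE)
  bf <- bayes_factor(ds, sp1, sp0, chains = 2, iter = 750, warmup = 100,
                     seed = 19)
  expect_true(bf$supports_interaction)
  expect_gt(bf$bf, 10)
})
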