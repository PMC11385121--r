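#' Arm-stratified train/test split
#'
#' Disjoint, exhaustive and reproducible: within each arm, a random
#' `floor((1 - train_frac) * n_arm)` patients form the test set and the
#' rest train (so the train fraction is met or slightly exceeded in each
#' arm; for the published cohort sizes at the default 0.60 this yields a
#' test set of 671).
#'
#' @param ds a `trial_cohort`.
#' @param train_frac training fraction (default 0.60).
#' @param seed integer seed.
#' @return list with `train` and `test` cohorts.
#' @export
split_train_test <- function(ds, train_frac = 0.60, seed = 1) {
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  test_idx <- integer(0)
  for (a in c("dopamine", "norepinephrine")) {
    rows <- which(ds$arm == a)
    n_test <- floor((1 - train_frac) * length(rows))
    test_idx <- c(test_idx, sample(rows, n_test))
  }
  test_idx <- sort(test_idx)
  list(train = ds[-test_idx, , drop = FALSE],
       test = ds[test_idx, , drop = FALSE])
}

#' Fit the S-learner outcome model on the training set
#'
#' A single Bayesian logistic model of the composite endpoint on age,
#' shock group, cardiomyopathy and total SOFA score, each interacting with
#' the intervention arm — queried later under both counterfactual arm
#' assignments to estimate per-patient effects. Age and SOFA enter
#' linearly and standardized; shock group is a three-level factor.
#'
#' @param train training cohort (derived endpoints present).
#' @param outcome endpoint column (default `"composite"`).
#' @param chains,iter,warmup,seed MCMC settings.
#' @return an `s_learner` wrapping the `bglm_fit`.
#' @export
fit_s_learner <- function(train, outcome = "composite", chains = 4,
                          iter = 1000, warmup = 100, seed = 1) {
  spec <- bglm_spec(outcome, "bernoulli_logit",
                    factor = "shock_group", interaction = TRUE,
                    covariates = c("age", "cardiomyopathy", "sofa_total"),
                    covariate_interaction = TRUE)
  fit <- bglm_fit(train, spec, chains, iter, warmup, seed = seed)
  check_fit_usable(fit)
  structure(list(fit = fit, outcome = outcome, n_train = nrow(train)),
            class = "s_learner")
}

#' Counterfactual individualized treatment-effect posteriors
#'
#' For every test patient and every posterior draw, predicts the composite
#' risk with the patient switched to dopamine and switched to
#' norepinephrine; the per-draw difference (dopamine minus norepinephrine)
#' is the individualized treatment-effect posterior. Patients carrying a
#' factor level unseen in training are flagged and get no estimate (they
#' still count in recommendation coverage denominators).
#'
#' @param model an [fit_s_learner()] result.
#' @param test test cohort.
#' @return an `ite_set`: tibble with per-patient median, HDI bounds,
#'   `p_benefit_norepi` = P(difference > 0), `p_benefit_dopa` =
#'   P(difference < 0), and an `excluded` flag; the per-draw difference
#'   matrix (patients x draws) is in `attr(, "draws")`.
#' @export
predict_counterfactuals <- function(model, test) {
  stopifnot(inherits(model, "s_learner"))
  fit <- model$fit
  ok <- rep(TRUE, nrow(test))
  if (!is.null(fit$spec$factor)) {
    f <- as.character(resolve_factor(test, fit$spec$factor))
    ok <- f %in% fit$design$factor_levels
  }
  sub <- test[ok, , drop = FALSE]
  X1 <- bglm_build_X(fit$design, sub, arm_override = 1)
  X0 <- bglm_build_X(fit$design, sub, arm_override = 0)
  beta <- fit$draws[, fit$param_names, drop = FALSE]
  K <- nrow(beta)
  dmat <- matrix(NA_real_, nrow(test), K)
  chunk <- max(1L, floor(4e6 / max(1L, nrow(sub))))
  for (s0 in seq(1L, K, by = chunk)) {
    idx <- s0:min(K, s0 + chunk - 1L)
    bt <- t(beta[idx, , drop = FALSE])
    dmat[ok, idx] <- plogis(X1 %*% bt) - plogis(X0 %*% bt)
  }
  summ <- tibble::tibble(
    id = test$id,
    excluded = !ok,
    median = apply(dmat, 1, function(d) if (all(is.na(d))) NA_real_ else median(d)),
    hdi_low = NA_real_, hdi_high = NA_real_,
    p_benefit_norepi = rowMeans(dmat > 0),
    p_benefit_dopa = rowMeans(dmat < 0)
  )
  for (i in which(ok)) {
    h <- hdi_interval(dmat[i, ])
    summ$hdi_low[i] <- h["lower"]; summ$hdi_high[i] <- h["upper"]
  }
  if (any(!ok))
    warning(sum(!ok), " test patient(s) with unseen factor levels excluded ",
            "from counterfactual prediction", call. = FALSE)
  structure(summ, draws = dmat, class = c("ite_set", class(summ)))
}

#' Apply the recommendation rule to individualized-effect posteriors
#'
#' Recommends norepinephrine for a patient when the posterior probability
#' that their composite risk is lower under norepinephrine exceeds the
#' threshold (and symmetrically for dopamine); otherwise no recommendation.
#' Coverage is the recommended fraction of the whole test set — patients
#' without an estimate count in the denominator as "none". The concordance
#' assessment downstream is only eligible when coverage reaches
#' `coverage_min`.
#'
#' @param ites an [predict_counterfactuals()] result.
#' @param threshold probability-of-benefit threshold (default 0.90).
#' @param coverage_min minimum coverage for outcome assessment
#'   (default 0.25).
#' @return a `recommendation_set`: per-patient recommendation, `coverage`,
#'   `assessment_eligible`.
#' @export
make_recommendations <- function(ites, threshold = 0.90, coverage_min = 0.25) {
  stopifnot(threshold > 0.5, threshold < 1)
  rec <- rep("none", nrow(ites))
  rec[!ites$excluded & ites$p_benefit_norepi > threshold] <- "norepinephrine"
  rec[!ites$excluded & ites$p_benefit_dopa > threshold] <- "dopamine"
  coverage <- mean(rec != "none")
  structure(list(
    recommendation = tibble::tibble(id = ites$id, recommendation = rec),
    threshold = threshold, coverage = coverage,
    n_norepinephrine = sum(rec == "norepinephrine"),
    n_dopamine = sum(rec == "dopamine"),
    n_none = sum(rec == "none"),
    n_excluded = sum(ites$excluded),
    assessment_eligible = coverage >= coverage_min
  ), class = "recommendation_set")
}

#' Assess outcomes under recommendation-concordant versus -discordant care
#'
#' Fits a Bayesian logistic model of the composite endpoint on
#' recommendation group, received arm and their interaction on the test
#' set, then reports the g-computation risk difference of receiving
#' dopamine versus norepinephrine within each recommendation group
#' (ROPE plus or minus 0.01). For the group recommended norepinephrine
#' this contrast reads as the cost of receiving the non-recommended drug.
#'
#' @param test test cohort (derived endpoints present).
#' @param recs a [make_recommendations()] result.
#' @param outcome endpoint column (default `"composite"`).
#' @param chains,iter,warmup,seed MCMC settings.
#' @param force run even if `recs` is not assessment-eligible.
#' @return list of per-group `posterior_summary` contrasts plus the fit.
#' @export
assess_recommendations <- function(test, recs, outcome = "composite",
                                   chains = 4, iter = 1000, warmup = 100,
                                   seed = 1, force = FALSE) {
  stopifnot(inherits(recs, "recommendation_set"))
  if (!recs$assessment_eligible && !force)
    stop("recommendation coverage ", sprintf("%.2f", recs$coverage),
         " is below the assessment-eligibility threshold", call. = FALSE)
  test$rec_group <- factor(recs$recommendation$recommendation[
    match(test$id, recs$recommendation$id)])
  groups <- levels(test$rec_group)
  single <- length(groups) == 1L
  spec <- bglm_spec(outcome, "bernoulli_logit",
                    factor = if (single) NULL else "rec_group",
                    interaction = !single)
  fit <- bglm_fit(test, spec, chains, iter, warmup, seed = seed)
  check_fit_usable(fit)
  contrasts <- list()
  for (g in groups) {
    cell <- table(test$arm[test$rec_group == g])
    if (length(cell) < 2L || any(cell == 0)) {
      warning("recommendation group '", g, "' has an empty arm cell; ",
              "contrast omitted", call. = FALSE)
      next
    }
    d <- if (single) marginal_effect(fit, "risk_difference")
         else marginal_effect(fit, "risk_difference", subgroup = g)
    contrasts[[g]] <- summarize_draws(d, rope = c(-0.01, 0.01))
  }
  list(contrasts = contrasts, fit = fit, groups = groups)
}
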