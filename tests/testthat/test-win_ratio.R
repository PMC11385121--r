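h1 <- hierarchy_death_rrt_arrhythmia()

test_that("pairwise comparison walks the hierarchy in order", {
  t_died <- list(death28 = TRUE, new_rrt = FALSE, new_arrhythmia = FALSE)
  c_surv <- list(death28 = FALSE, new_rrt = TRUE, new_arrhythmia = TRUE)
  r <- compare_pair(t_died, c_surv, h1)
  expect_identical(r$decision, "control_win"); expect_equal(r$level, 1L)

  t2 <- list(death28 = FALSE, new_rrt = FALSE, new_arrhythmia = TRUE)
  c2 <- list(death28 = FALSE, new_rrt = TRUE, new_arrhythmia = FALSE)
  r2 <- compare_pair(t2, c2, h1)
  expect_identical(r2$decision, "treatment_win"); expect_equal(r2$level, 2L)

  t3 <- list(death28 = FALSE, new_rrt = FALSE, new_arrhythmia = TRUE)
  c3 <- list(death28 = FALSE, new_rrt = FALSE, new_arrhythmia = TRUE)
  r3 <- compare_pair(t3, c3, h1)
  expect_identical(r3$decision, "tie"); expect_true(is.na(r3$level))

  expect_error(compare_pair(list(death28 = FALSE), c3, h1), "new_rrt.*level 2")
})

test_that("tie margins make near differences ties", {
  h <- hierarchy_death_los(tie_margin = 2)
  a <- list(death28 = FALSE, icu_los = 10)
  b <- list(death28 = FALSE, icu_los = 11)
  expect_identical(compare_pair(a, b, h)$decision, "tie")
  b$icu_los <- 13
  expect_identical(compare_pair(a, b, h)$decision, "treatment_win")
})

test_that("engine tallies equal exhaustive enumeration on random small cohorts", {
  for (s in 1:30) {
    ds <- toy_cohort(sample(5:30, 1), seed = 100 + s)
    for (h in list(h1, hierarchy_death_los(), hierarchy_death_los(3))) {
      wr <- suppressWarnings(
        compute_win_ratio(ds, h, strata = "none", ci = "asymptotic"))
      oracle <- brute_force_tally(ds, h)
      expect_equal(wr$pooled$wins_treatment, unname(oracle["wins_treatment"]))
      expect_equal(wr$pooled$wins_control, unname(oracle["wins_control"]))
      expect_equal(wr$pooled$ties, unname(oracle["ties"]))
    }
  }
})

test_that("per-level win counts sum to the totals and pairs are conserved", {
  ds <- toy_cohort(60, seed = 9)
  wr <- compute_win_ratio(ds, h1, strata = "shock_group", ci = "asymptotic")
  n_t <- sum(ds$arm == "dopamine"); n_c <- sum(ds$arm == "norepinephrine")
  for (s in wr$per_stratum) {
    expect_equal(sum(s$by_level$wins_treatment), s$wins_treatment)
    expect_equal(sum(s$by_level$wins_control), s$wins_control)
    expect_equal(s$wins_treatment + s$wins_control + s$ties,
                 s$n_treatment * s$n_control)
  }
  total_pairs <- sum(vapply(wr$per_stratum, function(s)
    s$n_treatment * s$n_control, 0))
  expect_equal(wr$pooled$wins_treatment + wr$pooled$wins_control +
                 wr$pooled$ties, total_pairs)
})

test_that("swapping arm labels inverts the win ratio exactly", {
  ds <- toy_cohort(40, seed = 21)
  flipped <- ds
  flipped$arm <- ifelse(ds$arm == "dopamine", "norepinephrine", "dopamine")
  a <- compute_win_ratio(ds, h1, strata = "shock_group", ci = "asymptotic")
  b <- compute_win_ratio(flipped, h1, strata = "shock_group", ci = "asymptotic")
  expect_equal(a$pooled$wins_treatment, b$pooled$wins_control)
  expect_equal(a$pooled$wins_control, b$pooled$wins_treatment)
  expect_equal(a$wr, 1 / b$wr)
})

test_that("a single stratum reproduces the unstratified tallies", {
  ds <- toy_cohort(35, seed = 33)
  ds$shock_type <- "septic"
  ds <- as_trial_cohort(tibble::as_tibble(ds))
  ds <- derive_endpoints(ds)
  a <- compute_win_ratio(ds, h1, strata = "none", ci = "asymptotic")
  b <- compute_win_ratio(ds, h1, strata = "shock_group", ci = "asymptotic")
  expect_equal(a$pooled, b$pooled)
  expect_equal(a$wr, b$wr)
})

test_that("an all-winning treatment arm reports an upper-unbounded win ratio", {
  df <- tibble::tibble(
    id = c("t1", "c1"), arm = c("dopamine", "norepinephrine"),
    shock_type = "septic", age = 60, sex = "m", apache2 = 20, sofa_total = 8,
    cardiomyopathy = FALSE, mech_vent = FALSE, baseline_rrt = FALSE,
    death28 = c(FALSE, TRUE), new_rrt = FALSE, new_arrhythmia = FALSE,
    icu_los = 5)
  ds <- derive_endpoints(as_trial_cohort(df))
  wr <- compute_win_ratio(ds, h1, strata = "none", ci = "bootstrap",
                          n_boot = 50, seed = 1)
  expect_equal(wr$pooled$wins_treatment, 1)
  expect_equal(wr$pooled$wins_control, 0)
  expect_true(wr$upper_unbounded)
})

test_that("identical outcome multisets give a win ratio near 1", {
  set.seed(14)
  base <- tibble::tibble(
    death28 = rep(c(TRUE, FALSE, FALSE, FALSE), 10),
    new_rrt = rep(c(FALSE, TRUE, FALSE, FALSE), 10),
    new_arrhythmia = rep(c(FALSE, FALSE, TRUE, FALSE), 10))
  df <- tibble::tibble(
    id = sprintf("x%02d", 1:80),
    arm = rep(c("dopamine", "norepinephrine"), each = 40),
    shock_type = "septic", age = 60, sex = "m", apache2 = 20, sofa_total = 8,
    cardiomyopathy = FALSE, mech_vent = FALSE, baseline_rrt = FALSE,
    death28 = c(base$death28, base$death28),
    new_rrt = c(base$new_rrt, base$new_rrt),
    new_arrhythmia = c(base$new_arrhythmia, base$new_arrhythmia),
    icu_los = 5)
  ds <- derive_endpoints(as_trial_cohort(df))
  wr <- compute_win_ratio(ds, h1, strata = "none", ci = "bootstrap",
                          n_boot = 400, seed = 2)
  expect_equal(wr$wr, 1)
  expect_gt(wr$p_value, 0.5)
})

test_that("a stratum with an empty arm is skipped with a warning", {
  ds <- toy_cohort(30, seed = 55)
  ds$shock_type[ds$shock_group == "cardiogenic"] <- "septic"
  ds$shock_type[1] <- "cardiogenic"  # row 1 is dopamine: cardiogenic has no control
  ds <- derive_endpoints(as_trial_cohort(tibble::as_tibble(ds)))
  expect_warning(
    wr <- compute_win_ratio(ds, h1, strata = "shock_group", ci = "asymptotic"),
    "empty arm")
  expect_false("cardiogenic" %in% names(wr$per_stratum))
})
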