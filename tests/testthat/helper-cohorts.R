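# Shared fixture builders and independent oracles, all generated in code.

# Small random cohort with both arms guaranteed; outcomes independent coin
# flips so ties and every hierarchy branch occur often.
toy_cohort <- function(n, seed) {
  set.seed(seed)
  arm <- c("dopamine", "norepinephrine",
           sample(c("dopamine", "norepinephrine"), n - 2, replace = TRUE))
  df <- tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    arm = arm,
    shock_type = sample(c("septic", "cardiogenic", "hypovolemic", "other"),
                        n, replace = TRUE),
    age = sample(30:90, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    apache2 = sample(5:40, n, replace = TRUE),
    sofa_total = sample(0:20, n, replace = TRUE),
    cardiomyopathy = sample(c(TRUE, FALSE), n, replace = TRUE),
    mech_vent = sample(c(TRUE, FALSE), n, replace = TRUE),
    baseline_rrt = FALSE,
    death28 = sample(c(TRUE, FALSE), n, replace = TRUE),
    new_rrt = sample(c(TRUE, FALSE), n, replace = TRUE),
    new_arrhythmia = sample(c(TRUE, FALSE), n, replace = TRUE),
    icu_los = sample(0:35, n, replace = TRUE)
  )
  derive_endpoints(as_trial_cohort(df, provenance = "test fixture"))
}

# Brute-force win/loss/tie tally by exhaustive pair enumeration through
# compare_pair() -- the independent oracle for the tally engine.
brute_force_tally <- function(ds, h) {
  df <- as.data.frame(ds)
  rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  ti <- which(df$arm == "dopamine"); ci <- which(df$arm != "dopamine")
  w <- l <- t_ <- 0
  for (i in ti) for (j in ci) {
    d <- compare_pair(rows[[i]], rows[[j]], h)$decision
    if (d == "treatment_win") w <- w + 1
    else if (d == "control_win") l <- l + 1
    else t_ <- t_ + 1
  }
  c(wins_treatment = w, wins_control = l, ties = t_)
}

# AUC by exhaustive pair enumeration (ties one half).
brute_force_auc <- function(pred, outcome) {
  pos <- pred[outcome]; neg <- pred[!outcome]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

write_temp_cohort_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

# Minimal well-formed 3-row cohort data frame for CSV round-trips.
csv_fixture_df <- function() {
  tibble::tibble(
    id = c("a", "b", "c"),
    arm = c("dopamine", "norepinephrine", "dopamine"),
    shock_type = c("septic", "cardiogenic", "hypovolemic"),
    age = c(70, 55, 61), sex = c("male", "female", "male"),
    apache2 = c(22, 18, 30), sofa_total = c(9, 7, 12),
    cardiomyopathy = c("yes", "no", "no"),
    mech_vent = c(1, 0, 1), baseline_rrt = c("false", "false", "true"),
    death28 = c("no", "no", "yes"),
    new_rrt = c(0, 0, 1), new_arrhythmia = c("true", "false", "false"),
    icu_los = c(35, 10, 3)
  )
}
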