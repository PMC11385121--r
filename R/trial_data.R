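#' @importFrom stats median quantile sd var cov qlogis plogis rnorm runif
#'   rgamma rchisq dnorm dt acf optim optimHess glm binomial coef
#'   qnorm pnorm qgamma setNames complete.cases relevel
#' @importFrom utils head tail
NULL

# Column schema for cohort CSV files.  `mandatory` must be present in the
# header; the six SOFA components and heart_rate are optional pass-through.
cohort_schema <- function() {
  list(
    mandatory = c(
      "id", "arm", "shock_type", "age", "sex", "apache2", "sofa_total",
      "cardiomyopathy", "mech_vent", "baseline_rrt",
      "death28", "new_rrt", "new_arrhythmia", "icu_los"
    ),
    logical = c("cardiomyopathy", "mech_vent", "baseline_rrt",
                "death28", "new_rrt", "new_arrhythmia"),
    numeric = c("age", "apache2", "sofa_total", "icu_los"),
    sofa_components = c("sofa_resp", "sofa_cardio", "sofa_coag",
                        "sofa_liver", "sofa_cns", "sofa_renal"),
    arms = c("dopamine", "norepinephrine"),
    shock_types = c("septic", "cardiogenic", "hypovolemic",
                    "anaphylactic", "other")
  )
}

#' Collapse raw shock type to the three analysis groups
#'
#' The analysis groups shock as septic, cardiogenic, and "other", where
#' "other" pools hypovolemic, anaphylactic and unclassified shock.
#'
#' @param shock_type character vector of raw shock types.
#' @return factor with levels `other`, `septic`, `cardiogenic`
#'   (reference level `other`).
#' @export
shock_group_of <- function(shock_type) {
  s <- tolower(trimws(as.character(shock_type)))
  g <- ifelse(s == "septic", "septic",
              ifelse(s == "cardiogenic", "cardiogenic", "other"))
  factor(g, levels = c("other", "septic", "cardiogenic"))
}

#' Construct a trial cohort from a data frame
#'
#' Validates and normalizes a patient-level two-arm cohort: one row per
#' randomized patient with arm, shock type, covariates and raw outcomes.
#' This is the single container every downstream stage consumes.
#'
#' @param df data frame with the documented columns (see [read_cohort()]).
#' @param provenance free-text source tag stored on the object.
#' @return a `trial_cohort` tibble with a derived `shock_group` column and
#'   attributes `provenance` and `derived` (which derived endpoints exist).
#' @export
as_trial_cohort <- function(df, provenance = "unspecified") {
  sch <- cohort_schema()
  missing_cols <- setdiff(sch$mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$arm <- tolower(trimws(as.character(df$arm)))
  df$shock_type <- tolower(trimws(as.character(df$shock_type)))
  for (col in sch$logical) df[[col]] <- parse_flexible_logical(df[[col]])
  for (col in sch$numeric) df[[col]] <- as.numeric(df[[col]])

  bad_arm <- which(!df$arm %in% sch$arms)
  bad_death <- which(is.na(df$death28))
  bad <- sort(union(bad_arm, bad_death))
  if (length(bad) > 0) {
    report <- tibble::tibble(
      row = bad,
      problem = ifelse(bad %in% bad_arm, "unparseable arm", "unparseable death28")
    )
    stop("cohort validation error: ", nrow(report), " row(s) rejected (",
         paste(sprintf("row %d: %s", report$row, report$problem), collapse = "; "),
         ")", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("cohort validation error: duplicate patient id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  }
  if (!all(sch$arms %in% df$arm)) {
    stop("cohort validation error: both arms must be present", call. = FALSE)
  }
  bad_shock <- !df$shock_type %in% sch$shock_types & !is.na(df$shock_type)
  if (any(bad_shock)) {
    stop("cohort validation error: unknown shock_type in row(s) ",
         paste(which(bad_shock), collapse = ", "), call. = FALSE)
  }
  df$shock_group <- shock_group_of(df$shock_type)

  comp <- intersect(sch$sofa_components, names(df))
  if (length(comp) == 6L) {
    ok <- complete.cases(df[comp]) & !is.na(df$sofa_total)
    mismatch <- ok & abs(rowSums(df[comp]) - df$sofa_total) > 1e-8
    if (any(mismatch)) {
      stop("cohort validation error: sofa_total differs from component sum in row(s) ",
           paste(which(mismatch), collapse = ", "), call. = FALSE)
    }
  }
  structure(df,
            class = c("trial_cohort", class(tibble::tibble()))) -> out
  attr(out, "provenance") <- provenance
  attr(out, "derived") <- character(0)
  out
}

#' Read a patient-level cohort from CSV
#'
#' Expects UTF-8 CSV, one row per patient, with mandatory columns `id`,
#' `arm` (dopamine / norepinephrine), `shock_type` (septic, cardiogenic,
#' hypovolemic, anaphylactic, other), `age`, `sex`, `apache2`, `sofa_total`,
#' `cardiomyopathy`, `mech_vent`, `baseline_rrt`, `death28`, `new_rrt`,
#' `new_arrhythmia`, `icu_los`. Booleans may be encoded as 0/1, true/false
#' or yes/no. Extra columns (e.g. the six SOFA components, `heart_rate`)
#' pass through untouched.
#'
#' @param path path to the CSV file.
#' @return a `trial_cohort` (see [as_trial_cohort()]).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trial_cohort(df, provenance = path)
}

#' Write a cohort (including derived endpoints) back to CSV
#' @param ds a `trial_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(ds), path)
  invisible(path)
}

#' Impute variables with low missingness
#'
#' Any variable whose missingness fraction is at most `max_frac` of the
#' sample size has missing continuous values replaced by the observed median
#' and missing categorical/logical values by the observed most common level;
#' variables above the threshold are left untouched and flagged in the
#' report. A tie for the most common level is broken by lexicographic level
#' order and recorded.
#'
#' @param ds a `trial_cohort`.
#' @param max_frac maximum missingness fraction eligible for imputation
#'   (default 0.01, i.e. up to 1% of the sample size).
#' @return the cohort with imputed values; the per-variable report is in
#'   `attr(, "imputation_report")`.
#' @export
impute_low_missingness <- function(ds, max_frac = 0.01) {
  stopifnot(max_frac > 0, max_frac < 1)
  n <- nrow(ds)
  rows <- list()
  for (col in setdiff(names(ds), c("id", "shock_group"))) {
    x <- ds[[col]]
    n_miss <- sum(is.na(x))
    if (n_miss == 0) next
    frac <- n_miss / n
    if (frac > max_frac) {
      rows[[col]] <- tibble::tibble(variable = col, n_missing = n_miss,
                                    frac = frac, action = "left untouched",
                                    fill = NA_character_, mode_tie = FALSE)
      next
    }
    if (is.numeric(x)) {
      fill <- median(x, na.rm = TRUE)
      ds[[col]][is.na(x)] <- fill
      rows[[col]] <- tibble::tibble(variable = col, n_missing = n_miss,
                                    frac = frac, action = "median imputed",
                                    fill = format(fill), mode_tie = FALSE)
    } else {
      tab <- table(as.character(x[!is.na(x)]))
      top <- names(tab)[tab == max(tab)]
      tie <- length(top) > 1
      fill_val <- sort(top)[1L]  # lexicographic tie-break, deterministic
      fill <- if (is.logical(x)) as.logical(fill_val) else fill_val
      ds[[col]][is.na(x)] <- fill
      rows[[col]] <- tibble::tibble(variable = col, n_missing = n_miss,
                                    frac = frac, action = "mode imputed",
                                    fill = fill_val, mode_tie = tie)
    }
  }
  report <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(variable = character(), n_missing = integer(),
                   frac = double(), action = character(),
                   fill = character(), mode_tie = logical())
  attr(ds, "imputation_report") <- report
  ds
}

#' Derive the composite endpoint and days alive and free of ICU
#'
#' `composite` is death by day 28, new renal replacement therapy, or new
#' arrhythmia. `daficu28` (days alive and free of ICU at 28 days) is 0 for
#' patients who die within 28 days; for survivors it is `28 - icu_los`
#' clamped into `[0, 28]` (ICU stays may exceed 28 days).
#'
#' Idempotent: re-deriving leaves an already-derived cohort unchanged.
#'
#' @param ds a `trial_cohort`.
#' @return the cohort with `composite` and `daficu28` columns.
#' @export
derive_endpoints <- function(ds) {
  need <- c("death28", "new_rrt", "new_arrhythmia", "icu_los")
  miss <- need[!need %in% names(ds)]
  if (length(miss)) stop("derive_endpoints: missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(ds$icu_los < 0, na.rm = TRUE)) {
    stop("derive_endpoints: negative icu_los in row(s) ",
         paste(which(ds$icu_los < 0), collapse = ", "), call. = FALSE)
  }
  ds$composite <- ds$death28 | ds$new_rrt | ds$new_arrhythmia
  ds$daficu28 <- ifelse(ds$death28, 0, pmin(28, pmax(0, 28 - ds$icu_los)))
  attr(ds, "derived") <- union(attr(ds, "derived") %||% character(0),
                               c("composite", "daficu28"))
  ds
}

#' Two-by-two table and unadjusted odds ratio for a binary endpoint
#'
#' Tabulates events by arm with dopamine events as cell `a`, and reports the
#' unadjusted odds ratio `(a*d)/(b*c)` with a Wald 95% confidence interval
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied: a zero cell yields an infinite or zero OR with an
#' explanatory note rather than a silently corrected value.
#'
#' @param ds a `trial_cohort`.
#' @param outcome name of a logical endpoint column (e.g. `"death28"`).
#' @return list with `a`, `b`, `c`, `d`, `odds_ratio`, `wald_ci_low`,
#'   `wald_ci_high`, `note`.
#' @export
two_by_two_summary <- function(ds, outcome = "death28") {
  if (!outcome %in% names(ds)) stop("unknown outcome column: ", outcome, call. = FALSE)
  y <- ds[[outcome]]
  if (!is.logical(y)) stop("outcome must be a logical endpoint", call. = FALSE)
  dopa <- ds$arm == "dopamine"
  a <- sum(y & dopa); b <- sum(!y & dopa)
  cc <- sum(y & !dopa); d <- sum(!y & !dopa)
  if (min(a, b, cc, d) == 0) {
    or <- (a * d) / (b * cc)  # may be 0, Inf or NaN; reported honestly
    return(list(a = a, b = b, c = cc, d = d, odds_ratio = or,
                wald_ci_low = NA_real_, wald_ci_high = NA_real_,
                note = "zero cell: no continuity correction applied, Wald CI undefined"))
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(a = a, b = b, c = cc, d = d, odds_ratio = or,
       wald_ci_low = exp(log(or) - 1.96 * se),
       wald_ci_high = exp(log(or) + 1.96 * se),
       note = NA_character_)
}

#' @export
print.trial_cohort <- function(x, ...) {
  cat(sprintf("<trial_cohort> %d patients (%d dopamine / %d norepinephrine), source: %s\n",
              nrow(x), sum(x$arm == "dopamine"), sum(x$arm == "norepinephrine"),
              attr(x, "provenance") %||% "?"))
  der <- attr(x, "derived")
  if (length(der)) cat("derived endpoints:", paste(der, collapse = ", "), "\n")
  NextMethod()
}
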