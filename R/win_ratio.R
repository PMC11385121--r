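#' Construct an ordered endpoint hierarchy for pairwise comparisons
#'
#' Each level names an endpoint column, its type, which direction wins, and
#' a tie margin: at a continuous level the favoured patient wins only when
#' the absolute difference exceeds `tie_margin`. Levels are consulted in
#' order until a pair is decided; a pair tied after the last level is a
#' final tie (there is no early stopping).
#'
#' @param ... one or more levels created by [hierarchy_level()].
#' @return an `endpoint_hierarchy`.
#' @export
endpoint_hierarchy <- function(...) {
  levels <- list(...)
  if (length(levels) < 1L) stop("hierarchy needs at least one level", call. = FALSE)
  for (l in levels) {
    stopifnot(inherits(l, "hierarchy_level"))
  }
  structure(list(levels = levels), class = "endpoint_hierarchy")
}

#' @rdname endpoint_hierarchy
#' @param endpoint endpoint column name.
#' @param type `"binary"` or `"continuous"`.
#' @param direction `"lower_wins"` (e.g. death, ICU length of stay) or
#'   `"higher_wins"` (e.g. days alive and free of ICU).
#' @param tie_margin non-negative numeric; differences of at most this size
#'   are ties passed to the next level.
#' @export
hierarchy_level <- function(endpoint, type = c("binary", "continuous"),
                            direction = c("lower_wins", "higher_wins"),
                            tie_margin = 0) {
  type <- match.arg(type); direction <- match.arg(direction)
  stopifnot(is.character(endpoint), length(endpoint) == 1L, tie_margin >= 0)
  if (type == "binary" && tie_margin != 0)
    stop("binary levels must have tie_margin 0", call. = FALSE)
  structure(list(endpoint = endpoint, type = type, direction = direction,
                 tie_margin = tie_margin), class = "hierarchy_level")
}

#' Primary hierarchy: death, then new renal replacement, then new arrhythmia
#' @return an `endpoint_hierarchy`.
#' @export
hierarchy_death_rrt_arrhythmia <- function() {
  endpoint_hierarchy(
    hierarchy_level("death28", "binary", "lower_wins"),
    hierarchy_level("new_rrt", "binary", "lower_wins"),
    hierarchy_level("new_arrhythmia", "binary", "lower_wins")
  )
}

#' Secondary hierarchy: death, then ICU length of stay
#'
#' Among pairs tied on death, the patient with the shorter ICU stay wins
#' (a shorter stay is favourable, making this hierarchy conceptually close
#' to days alive and free of ICU). Tie margin defaults to 0 days.
#'
#' @param tie_margin tie margin in days for the length-of-stay level.
#' @return an `endpoint_hierarchy`.
#' @export
hierarchy_death_los <- function(tie_margin = 0) {
  endpoint_hierarchy(
    hierarchy_level("death28", "binary", "lower_wins"),
    hierarchy_level("icu_los", "continuous", "lower_wins", tie_margin)
  )
}

# Values matrix (patients x levels) in canonical "smaller value wins" form.
hierarchy_values <- function(ds, h) {
  L <- length(h$levels)
  out <- matrix(NA_real_, nrow(ds), L)
  for (k in seq_len(L)) {
    lv <- h$levels[[k]]
    if (!lv$endpoint %in% names(ds))
      stop("hierarchy endpoint not found in cohort: ", lv$endpoint, call. = FALSE)
    v <- as.numeric(ds[[lv$endpoint]])
    if (anyNA(v))
      stop("missing values in hierarchy endpoint ", lv$endpoint, " (rows ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "), ")", call. = FALSE)
    out[, k] <- if (lv$direction == "higher_wins") -v else v
  }
  out
}

#' Compare one treatment/control patient pair over a hierarchy
#'
#' Reference implementation of the pairwise rule, used directly and as the
#' brute-force oracle for the vectorized tally engine: levels are evaluated
#' in order; at each level the favoured patient wins if the difference
#' exceeds the tie margin, otherwise the pair passes to the next level; a
#' pair undecided after the last level is a tie.
#'
#' @param t,c single patient rows (lists or one-row data frames) carrying
#'   the hierarchy endpoints.
#' @param h an [endpoint_hierarchy()].
#' @return list with `decision` (`"treatment_win"`, `"control_win"` or
#'   `"tie"`) and `level` (deciding level index, `NA` for a final tie).
#' @export
compare_pair <- function(t, c, h) {
  for (k in seq_along(h$levels)) {
    lv <- h$levels[[k]]
    tv <- t[[lv$endpoint]]; cv <- c[[lv$endpoint]]
    if (is.null(tv) || is.null(cv) || is.na(tv) || is.na(cv))
      stop("endpoint ", lv$endpoint, " missing at level ", k, call. = FALSE)
    d <- as.numeric(tv) - as.numeric(cv)
    if (lv$direction == "higher_wins") d <- -d
    if (d < -lv$tie_margin) return(list(decision = "treatment_win", level = k))
    if (d > lv$tie_margin) return(list(decision = "control_win", level = k))
  }
  list(decision = "tie", level = NA_integer_)
}

# --- tally engines ----------------------------------------------------------
# Fast path: recursion over levels. At a margin-0 level, wins are counted by
# sorted rank queries and pairs tied at the level (equal values) recurse as
# groups -- O(n log n) per stratum. A level with tie_margin > 0 is handled by
# direct counting when terminal; a non-terminal margin level falls back to
# dense pair enumeration (margin ties are not transitive, so groups cannot
# recurse).

new_tally_acc <- function(n_t, n_c, L, patient) {
  acc <- new.env(parent = emptyenv())
  acc$wins_t <- numeric(L); acc$wins_c <- numeric(L); acc$ties <- 0
  acc$patient <- patient
  if (patient) {
    acc$t_wins <- numeric(n_t); acc$t_loss <- numeric(n_t)
    acc$c_wins <- numeric(n_c); acc$c_loss <- numeric(n_c)
  }
  acc
}

tally_recurse <- function(vt, vc, margins, it, ic, lev, acc) {
  L <- ncol(vt)
  if (length(it) == 0L || length(ic) == 0L) return(invisible())
  if (lev > L) {
    acc$ties <- acc$ties + length(it) * length(ic)
    return(invisible())
  }
  x <- vt[it, lev]; y <- vc[ic, lev]
  m <- margins[lev]
  if (m == 0) {
    ys <- sort(y); xs <- sort(x)
    n_le <- findInterval(x, ys)                    # y <= x
    n_lt <- findInterval(x, ys, left.open = TRUE)  # y <  x
    w_i <- length(y) - n_le   # controls with larger value -> t wins
    l_i <- n_lt               # controls with smaller value -> c wins
    acc$wins_t[lev] <- acc$wins_t[lev] + sum(w_i)
    acc$wins_c[lev] <- acc$wins_c[lev] + sum(l_i)
    if (acc$patient) {
      acc$t_wins[it] <- acc$t_wins[it] + w_i
      acc$t_loss[it] <- acc$t_loss[it] + l_i
      yc_le <- findInterval(y, xs)                          # x <= y
      yc_lt <- findInterval(y, xs, left.open = TRUE)        # x <  y
      acc$c_wins[ic] <- acc$c_wins[ic] + (length(x) - yc_le)  # t with larger value
      acc$c_loss[ic] <- acc$c_loss[ic] + yc_lt
    }
    shared <- intersect(unique(x), unique(y))
    for (v in shared) {
      tally_recurse(vt, vc, margins, it[x == v], ic[y == v], lev + 1L, acc)
    }
    # tied pairs whose value appears on only one side cannot exist: a tie at
    # a margin-0 level means exactly equal values.
  } else if (lev == L) {
    ys <- sort(y); xs <- sort(x)
    w_i <- length(y) - findInterval(x + m, ys)             # y >  x + m
    l_i <- findInterval(x - m, ys, left.open = TRUE)       # y <  x - m
    acc$wins_t[lev] <- acc$wins_t[lev] + sum(w_i)
    acc$wins_c[lev] <- acc$wins_c[lev] + sum(l_i)
    acc$ties <- acc$ties + length(x) * length(y) - sum(w_i) - sum(l_i)
    if (acc$patient) {
      acc$t_wins[it] <- acc$t_wins[it] + w_i
      acc$t_loss[it] <- acc$t_loss[it] + l_i
      wc_j <- length(x) - findInterval(y + m, xs)
      lc_j <- findInterval(y - m, xs, left.open = TRUE)
      acc$c_wins[ic] <- acc$c_wins[ic] + wc_j
      acc$c_loss[ic] <- acc$c_loss[ic] + lc_j
    }
  } else {
    tally_dense(vt, vc, margins, it, ic, lev, acc)
  }
  invisible()
}

tally_dense <- function(vt, vc, margins, it, ic, lev0, acc) {
  L <- ncol(vt)
  und <- matrix(TRUE, length(it), length(ic))
  for (lev in lev0:L) {
    d <- outer(vt[it, lev], vc[ic, lev], "-")
    m <- margins[lev]
    winT <- und & (d < -m); winC <- und & (d > m)
    acc$wins_t[lev] <- acc$wins_t[lev] + sum(winT)
    acc$wins_c[lev] <- acc$wins_c[lev] + sum(winC)
    if (acc$patient) {
      acc$t_wins[it] <- acc$t_wins[it] + rowSums(winT)
      acc$t_loss[it] <- acc$t_loss[it] + rowSums(winC)
      acc$c_wins[ic] <- acc$c_wins[ic] + colSums(winC)
      acc$c_loss[ic] <- acc$c_loss[ic] + colSums(winT)
    }
    und <- und & !winT & !winC
  }
  acc$ties <- acc$ties + sum(und)
  invisible()
}

# Tally all treatment x control pairs for one stratum.
tally_stratum <- function(vt, vc, margins, patient = FALSE) {
  acc <- new_tally_acc(nrow(vt), nrow(vc), ncol(vt), patient)
  tally_recurse(vt, vc, margins, seq_len(nrow(vt)), seq_len(nrow(vc)), 1L, acc)
  acc
}

#' Stratified win ratio over an endpoint hierarchy
#'
#' Forms every treatment (dopamine) versus control (norepinephrine) patient
#' pair within each stratum, tallies wins, losses and ties over the
#' hierarchy, and pools strata by summed win counts: the pooled win ratio
#' is total treatment wins over total control wins. A win ratio below 1
#' means the treatment arm accumulated fewer wins. Inference is by a
#' patient-level bootstrap (resampling within arm-by-stratum cells) by
#' default, with an asymptotic log-win-ratio variance (two-sample
#' U-statistic estimator) available for cross-checking.
#'
#' @param ds a derived `trial_cohort`.
#' @param h an [endpoint_hierarchy()].
#' @param strata `"shock_group"` (default) or `"none"`.
#' @param ci `"bootstrap"` (percentile, default) or `"asymptotic"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return a `win_ratio_result`: per-stratum and pooled tallies with
#'   per-level breakdowns, `wr`, `ci_low`, `ci_high`, `p_value`,
#'   `ci_method`.
#' @export
compute_win_ratio <- function(ds, h, strata = c("shock_group", "none"),
                              ci = c("bootstrap", "asymptotic"),
                              n_boot = 2000, seed = 1) {
  strata <- match.arg(strata); ci <- match.arg(ci)
  vals <- hierarchy_values(ds, h)
  margins <- vapply(h$levels, function(l) l$tie_margin, numeric(1))
  grp <- if (strata == "none") rep("all", nrow(ds)) else as.character(ds$shock_group)
  is_t <- ds$arm == "dopamine"

  keep <- character(0)
  for (g in unique(grp)) {
    if (sum(is_t & grp == g) == 0L || sum(!is_t & grp == g) == 0L) {
      warning("stratum '", g, "' has an empty arm; skipped", call. = FALSE)
    } else keep <- c(keep, g)
  }
  if (length(keep) == 0L) stop("no stratum with both arms present", call. = FALSE)

  per_stratum <- list()
  W <- 0; Lw <- 0; Ties <- 0
  by_level_t <- numeric(ncol(vals)); by_level_c <- numeric(ncol(vals))
  var_W <- 0; var_L <- 0; cov_WL <- 0
  for (g in keep) {
    ti <- which(is_t & grp == g); cj <- which(!is_t & grp == g)
    acc <- tally_stratum(vals[ti, , drop = FALSE], vals[cj, , drop = FALSE],
                         margins, patient = TRUE)
    nt <- length(ti); nc <- length(cj)
    per_stratum[[g]] <- list(
      stratum = g, n_treatment = nt, n_control = nc,
      wins_treatment = sum(acc$wins_t), wins_control = sum(acc$wins_c),
      ties = acc$ties,
      by_level = tibble::tibble(level = seq_along(margins),
                                endpoint = vapply(h$levels, `[[`, "", "endpoint"),
                                wins_treatment = acc$wins_t,
                                wins_control = acc$wins_c)
    )
    W <- W + sum(acc$wins_t); Lw <- Lw + sum(acc$wins_c); Ties <- Ties + acc$ties
    by_level_t <- by_level_t + acc$wins_t; by_level_c <- by_level_c + acc$wins_c
    # two-sample U-statistic variance components for (theta_w, theta_l)
    vw <- var(acc$t_wins / nc) / nt + var(acc$c_loss / nt) / nc
    vl <- var(acc$t_loss / nc) / nt + var(acc$c_wins / nt) / nc
    cwl <- cov(acc$t_wins / nc, acc$t_loss / nc) / nt +
      cov(acc$c_loss / nt, acc$c_wins / nt) / nc
    var_W <- var_W + (nt * nc)^2 * vw
    var_L <- var_L + (nt * nc)^2 * vl
    cov_WL <- cov_WL + (nt * nc)^2 * cwl
  }

  wr <- if (Lw > 0) W / Lw else Inf
  if (ci == "asymptotic") {
    if (W == 0 || Lw == 0) {
      ci_low <- NA_real_; ci_high <- NA_real_; p <- NA_real_
    } else {
      se <- sqrt(var_W / W^2 + var_L / Lw^2 - 2 * cov_WL / (W * Lw))
      ci_low <- exp(log(wr) - 1.96 * se); ci_high <- exp(log(wr) + 1.96 * se)
      p <- 2 * pnorm(-abs(log(wr) / se))
    }
  } else {
    set.seed(seed)
    lw_boot <- numeric(n_boot)
    idx_t <- lapply(keep, function(g) which(is_t & grp == g))
    idx_c <- lapply(keep, function(g) which(!is_t & grp == g))
    for (b in seq_len(n_boot)) {
      Wb <- 0; Lb <- 0
      for (s in seq_along(keep)) {
        ti <- sample(idx_t[[s]], length(idx_t[[s]]), replace = TRUE)
        cj <- sample(idx_c[[s]], length(idx_c[[s]]), replace = TRUE)
        acc <- tally_stratum(vals[ti, , drop = FALSE], vals[cj, , drop = FALSE],
                             margins, patient = FALSE)
        Wb <- Wb + sum(acc$wins_t); Lb <- Lb + sum(acc$wins_c)
      }
      lw_boot[b] <- if (Wb > 0 && Lb > 0) log(Wb / Lb) else
        log((Wb + 0.5) / (Lb + 0.5))
    }
    qs <- quantile(exp(lw_boot), c(0.025, 0.975), names = FALSE)
    ci_low <- qs[1]; ci_high <- qs[2]
    p <- min(1, 2 * min((1 + sum(lw_boot <= 0)) / (1 + n_boot),
                        (1 + sum(lw_boot >= 0)) / (1 + n_boot)))
  }

  structure(list(
    hierarchy = h, strata = strata, per_stratum = per_stratum,
    pooled = list(wins_treatment = W, wins_control = Lw, ties = Ties,
                  by_level = tibble::tibble(
                    level = seq_along(margins),
                    endpoint = vapply(h$levels, `[[`, "", "endpoint"),
                    wins_treatment = by_level_t, wins_control = by_level_c)),
    wr = wr, ci_low = ci_low, ci_high = ci_high, p_value = p,
    ci_method = ci, n_boot = if (ci == "bootstrap") n_boot else NA_integer_,
    upper_unbounded = !is.finite(wr)
  ), class = "win_ratio_result")
}

#' @export
print.win_ratio_result <- function(x, ...) {
  cat(sprintf("Win ratio (treatment = dopamine): %s\n",
              if (is.finite(x$wr)) sprintf("%.3f", x$wr) else "upper-unbounded"))
  cat(sprintf("  95%% CI (%s): %.3f - %.3f; two-sided p = %.4g\n",
              x$ci_method, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  pooled wins T/C/ties: %d / %d / %d over %d strat%s\n",
              as.integer(x$pooled$wins_treatment), as.integer(x$pooled$wins_control),
              as.integer(x$pooled$ties), length(x$per_stratum),
              if (length(x$per_stratum) == 1) "um" else "a"))
  invisible(x)
}
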