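#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' Every stochastic stage of the pipeline draws its own seed from a single
#' master seed and a short label, so that re-running one stage never perturbs
#' another. The derivation is a small deterministic integer hash kept below
#' 2^31 (R integers are 32-bit).
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) %% 1000003L) * 1009L + h * 31L) %% 2147483647L
}

#' Numerically stable log(1 + exp(x))
#' @noRd
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' Highest-density interval of a draw vector
#'
#' Narrowest-interval algorithm over the sorted draws: among all windows
#' containing `mass` of the draws, return the one with smallest width.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass interval probability mass (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
hdi_interval <- function(draws, mass = 0.95) {
  stopifnot(is.numeric(draws), length(draws) >= 1L, mass > 0, mass < 1)
  if (length(draws) == 1L) return(c(lower = draws, upper = draws))
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Parse flexible boolean encodings used in cohort CSV files
#'
#' Accepts 0/1, true/false, yes/no (any case). Anything else is NA.
#' @noRd
parse_flexible_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    out <- rep(NA, length(x))
    out[x == 0] <- FALSE
    out[x == 1] <- TRUE
    return(out)
  }
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[s %in% c("0", "false", "no", "f", "n")] <- FALSE
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
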