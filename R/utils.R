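# Small internal numerics shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of y(x) over the full range of x
#' @noRd
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Cumulative trapezoidal integral, same length as x, starting at 0
#' @noRd
cumtrapz_int <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

#' Standardize to zero mean, unit SD; errors on flat input
#' @noRd
zscore <- function(x, label = "signal") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(label, " has zero variance; cannot standardize", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Truncated-normal draws, truncation at +/- 3 SD (mean preserved)
#' @noRd
rtrunc_norm3 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(-3), stats::pnorm(3))
  mean + sd * stats::qnorm(u)
}
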