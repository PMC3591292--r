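# Small closed-form statistics for interpreting variance-component
# estimates near the zero boundary and comparing estimates between
# independent studies.

#' Two-sided z-test for the difference of two independent estimates
#'
#' Treats both (estimate, SE) pairs as independent normal estimators, e.g.
#' SNP-heritability estimates from non-overlapping cohorts.
#'
#' @param a,b numeric vectors c(estimate, se), or lists with `estimate`
#'   and `se` elements; `se` must be positive.
#' @return two-sided normal p-value.
#' @export
z_diff_test <- function(a, b) {
  a <- as_est_se(a); b <- as_est_se(b)
  z <- (a$estimate - b$estimate) / sqrt(a$se^2 + b$se^2)
  2 * stats::pnorm(-abs(z))
}

#' Two-sided z-test of a deviation against its standard error
#'
#' E.g. the deviation of one chromosome's estimate from a fitted
#' length-proportionality line.
#'
#' @param deviation observed deviation.
#' @param se its standard error (> 0).
#' @return two-sided normal p-value.
#' @export
z_dev_test <- function(deviation, se) {
  if (se <= 0) stop("se must be positive")
  2 * stats::pnorm(-abs(deviation / se))
}

#' Probability that a boundary-constrained estimate is zero
#'
#' For a variance ratio with true value `true_value` and a normally
#' distributed estimator with standard error `se`, constrained at the zero
#' boundary: the probability of observing a zero estimate is
#' Phi(-true_value / se). A true value of 0.05 with SE 0.04 gives ~0.11,
#' i.e. a few zero estimates among dozens of traits are unsurprising even
#' when no true value is zero.
#'
#' @param true_value true parameter value (fraction scale).
#' @param se standard error of the estimator (> 0).
#' @return probability in (0, 1).
#' @export
prob_zero_estimate <- function(true_value, se) {
  if (se <= 0) stop("se must be positive")
  stats::pnorm(-true_value / se)
}

#' Large-sample standard error of a regression R-squared
#'
#' Uses the approximation var(R^2) = 4 rho^2 (1 - rho^2) / N for the
#' sampling variance of a regression R-squared with expectation rho^2 and
#' N observations.
#'
#' @param rho2 population squared correlation, in [0, 1].
#' @param N number of observations (>= 2).
#' @return approximate standard error of R-squared.
#' @export
r2_sampling_se <- function(rho2, N) {
  if (rho2 < 0 || rho2 > 1) stop("rho2 must be in [0, 1]")
  if (N < 2) stop("N must be >= 2")
  sqrt(4 * rho2 * (1 - rho2) / N)
}

as_est_se <- function(x) {
  if (is.list(x)) {
    est <- x$estimate; se <- x$se
  } else {
    est <- x[1]; se <- x[2]
  }
  if (is.na(se) || se <= 0) stop("se must be positive")
  list(estimate = est, se = se)
}
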