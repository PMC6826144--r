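# Analytic MR power via the normal (non-centrality) approximation used by the
# mRnd web tool. Calibration against the published power column fixes the
# critical-value convention: one-sided Phi^-1(1 - alpha) for binary outcomes,
# two-sided Phi^-1(1 - alpha/2) for continuous outcomes. Both conventions are
# available behind the `sided` argument.

#' Analytic MR power for a binary outcome
#'
#' Normal approximation
#' `Phi( sqrt(n * r2 * K * (1 - K)) * |log(OR)| - z_crit )`, where `r2` is the
#' exposure variance explained by the instruments, `K` the case fraction and
#' `OR` the detectable odds ratio per SD of exposure.
#'
#' @param n sample size.
#' @param cases number of cases (used with `n` to form K) or `NULL` if `K`
#'   given directly.
#' @param K case fraction in (0, 1); computed from `cases / n` when omitted.
#' @param or detectable odds ratio per SD of exposure (default 1.2).
#' @param r2 instrument variance explained (default 0.0223).
#' @param alpha significance level (default 0.01).
#' @param sided critical-value convention; `1` (default, calibrated) uses
#'   `qnorm(1 - alpha)`, `2` uses `qnorm(1 - alpha / 2)`.
#' @return power in (0, 1).
#' @export
power_binary <- function(n, cases = NULL, K = NULL, or = 1.2, r2 = 0.0223,
                         alpha = 0.01, sided = 1) {
  if (is.null(K)) {
    if (is.null(cases)) abort("ValidationError", "supply either cases or K")
    K <- cases / n
  }
  if (any(K <= 0 | K >= 1)) abort("ValidationError", "K must lie in (0, 1)")
  if (r2 <= 0 || r2 >= 1) abort("ValidationError", "r2 must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("ValidationError", "alpha must lie in (0, 1)")
  z <- if (sided == 1) stats::qnorm(1 - alpha) else stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(n * r2 * K * (1 - K)) * abs(log(or)) - z)
}

#' Analytic MR power for a continuous outcome
#'
#' Normal approximation `Phi( sqrt(n * r2) * |beta| - z_crit )` for a
#' detectable effect of `beta` SD of outcome per SD of exposure.
#'
#' @param n sample size.
#' @param beta detectable effect, SD of outcome per SD of exposure
#'   (default 0.1).
#' @param r2 instrument variance explained (default 0.0223).
#' @param alpha significance level (default 0.01).
#' @param sided critical-value convention; `2` (default, calibrated) uses
#'   `qnorm(1 - alpha / 2)`.
#' @return power in (0, 1).
#' @export
power_continuous <- function(n, beta = 0.1, r2 = 0.0223, alpha = 0.01,
                             sided = 2) {
  if (r2 <= 0 || r2 >= 1) abort("ValidationError", "r2 must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) abort("ValidationError", "alpha must lie in (0, 1)")
  z <- if (sided == 1) stats::qnorm(1 - alpha) else stats::qnorm(1 - alpha / 2)
  stats::pnorm(sqrt(n * r2) * abs(beta) - z)
}

#' Low-power flag
#'
#' Outcomes with power strictly below the threshold (80% by default) are
#' considered low-powered for the stated detectable effect.
#'
#' @param power power value(s) in [0, 1].
#' @param threshold flagging threshold (default 0.80, strict).
#' @return logical.
#' @export
flag_low_power <- function(power, threshold = 0.80) {
  power < threshold
}

#' Power table for a set of outcomes
#'
#' @param tab data.frame with columns `outcome`, `n`, and `cases` (NA for
#'   continuous outcomes, where `beta` applies).
#' @param or,beta,r2,alpha see [power_binary()] / [power_continuous()].
#' @return `tab` with `power` and `low_power` columns appended.
#' @export
power_table <- function(tab, or = 1.2, beta = 0.1, r2 = 0.0223, alpha = 0.01) {
  cont <- is.na(tab$cases)
  tab$power <- NA_real_
  if (any(cont))
    tab$power[cont] <- power_continuous(tab$n[cont], beta = beta, r2 = r2,
                                        alpha = alpha)
  if (any(!cont))
    tab$power[!cont] <- power_binary(tab$n[!cont], cases = tab$cases[!cont],
                                     or = or, r2 = r2, alpha = alpha)
  tab$low_power <- flag_low_power(tab$power)
  tab
}
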