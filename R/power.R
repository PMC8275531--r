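# Analytic non-centrality-parameter power for two-sample MR with a binary
# outcome, and its closed-form inversion to a minimal detectable odds ratio.

check_power_cfg <- function(n_outcome, case_fraction, r2, alpha) {
  if (!is.numeric(n_outcome) || n_outcome < 1) {
    mr_error("n_outcome must be a positive sample size", "mr_domain_error")
  }
  if (!is.numeric(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
    mr_error("case_fraction must lie in (0, 1)", "mr_domain_error")
  }
  if (n_outcome * case_fraction < 1) {
    mr_error("n_outcome * case_fraction must be at least 1", "mr_domain_error")
  }
  if (!is.numeric(r2) || r2 <= 0 || r2 >= 1) {
    mr_error("r2 must lie strictly in (0, 1)", "mr_domain_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    mr_error("alpha must lie in (0, 1)", "mr_domain_error")
  }
}

#' Power to detect a causal odds ratio in two-sample MR
#'
#' Non-centrality-parameter approximation for a binary outcome: with
#' `b = |log(odds_ratio)|` per unit (e.g. per SD) of exposure, `NCP =
#' n_outcome * r2 * K * (1 - K) * b^2` where `K` is the case fraction and
#' `r2` the exposure variance explained by the instrument, and
#' `power = Phi(sqrt(NCP) - z_{1 - alpha/2})`.
#'
#' @param odds_ratio Causal odds ratio per unit exposure (vectorised).
#' @param n_outcome Outcome-study sample size.
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2 Exposure variance explained by the instrument.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1); symmetric in `odds_ratio` and its reciprocal.
#' @examples
#' mr_power_binary(1.27, n_outcome = 53293, case_fraction = 19099 / 53293,
#'                 r2 = 0.0284)
#' @export
mr_power_binary <- function(odds_ratio, n_outcome, case_fraction, r2,
                            alpha = 0.05) {
  check_power_cfg(n_outcome, case_fraction, r2, alpha)
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    mr_error("odds_ratio must be positive", "mr_domain_error")
  }
  b <- abs(log(odds_ratio))
  ncp <- n_outcome * r2 * case_fraction * (1 - case_fraction) * b^2
  pnorm(sqrt(ncp) - qnorm(1 - alpha / 2))
}

#' Minimal detectable odds ratio at a target power
#'
#' Closed-form inversion of [mr_power_binary()]:
#' `b = (z_{1 - alpha/2} + z_power) / sqrt(n_outcome * r2 * K * (1 - K))`,
#' returned as `exp(b) > 1`.
#'
#' @param target_power Desired power, in (0, 1).
#' @inheritParams mr_power_binary
#' @return The smallest odds ratio above 1 detectable at `target_power`.
#' @examples
#' mr_detectable_or(0.80, n_outcome = 53293, case_fraction = 19099 / 53293,
#'                  r2 = 0.0284)
#' @export
mr_detectable_or <- function(target_power, n_outcome, case_fraction, r2,
                             alpha = 0.05) {
  check_power_cfg(n_outcome, case_fraction, r2, alpha)
  if (any(target_power <= 0) || any(target_power >= 1)) {
    mr_error("target_power must lie in (0, 1)", "mr_domain_error")
  }
  b <- (qnorm(1 - alpha / 2) + qnorm(target_power)) /
    sqrt(n_outcome * r2 * case_fraction * (1 - case_fraction))
  exp(b)
}
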