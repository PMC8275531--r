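# Synthetic paired two-sample summary statistics with known ground truth:
# linear structural model beta_Y = theta * gamma + alpha plus sampling noise,
# generated directly on the summary level.

NON_PALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                                  "C", "A", "C", "T", "G", "A", "G", "T"),
                                ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Define a synthetic two-sample MR scenario
#'
#' Ground-truth parameters for [simulate_two_sample()]. The defaults emulate
#' the study conditions of the bundled vitamin D / ADHD analysis: six
#' instruments with exposure effects of Table-1-like magnitude (mean 0.04, sd
#' 0.03 per allele on the log-exposure scale), an exposure GWAS of 79,366
#' individuals, a binary outcome study of 53,293 with case fraction
#' 19,099/53,293, and no causal effect or pleiotropy.
#'
#' @param n_snps Number of instruments J.
#' @param theta True causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd Mean and sd of the per-SNP exposure effects.
#' @param n_exposure,n_outcome Sample sizes of the two studies.
#' @param case_fraction Case proportion of a binary outcome, or `NULL` for a
#'   continuous outcome.
#' @param pleiotropy_mean,pleiotropy_sd Mean and sd of the direct (pleiotropic)
#'   SNP-outcome effects alpha.
#' @param inside_rho Correlation between alpha and gamma in \[-1, 1\]; nonzero
#'   values violate the InSIDE assumption.
#' @param palindromic_fraction Fraction of instruments given palindromic
#'   alleles.
#' @param missing_in_outcome Number of instruments deleted from the outcome
#'   table.
#' @param seed Generator seed.
#' @return List of class `mr_scenario`.
#' @export
mr_scenario <- function(n_snps = 6L, theta = 0,
                        gamma_mean = 0.04, gamma_sd = 0.03,
                        n_exposure = 79366L, n_outcome = 53293L,
                        case_fraction = 19099 / 53293,
                        pleiotropy_mean = 0, pleiotropy_sd = 0,
                        inside_rho = 0, palindromic_fraction = 0,
                        missing_in_outcome = 0L, seed = 1L) {
  if (n_snps < 1L) mr_error("n_snps must be >= 1", "mr_domain_error")
  if (gamma_sd < 0 || pleiotropy_sd < 0) {
    mr_error("standard deviations must be >= 0", "mr_domain_error")
  }
  if (abs(inside_rho) > 1) mr_error("|inside_rho| must be <= 1", "mr_domain_error")
  if (palindromic_fraction < 0 || palindromic_fraction > 1) {
    mr_error("palindromic_fraction must lie in [0, 1]", "mr_domain_error")
  }
  if (missing_in_outcome > n_snps) {
    mr_error("missing_in_outcome cannot exceed n_snps", "mr_domain_error")
  }
  if (!is.null(case_fraction) &&
      (case_fraction <= 0 || case_fraction >= 1)) {
    mr_error("case_fraction must lie in (0, 1) or be NULL", "mr_domain_error")
  }
  structure(as.list(environment()), class = "mr_scenario")
}

# per-variant standard error of the outcome association: standard GWAS
# approximation with unit trait variance (continuous) or log-odds (binary)
outcome_se <- function(eaf, n, case_fraction) {
  denom <- 2 * eaf * (1 - eaf) * n
  if (!is.null(case_fraction)) {
    denom <- denom * case_fraction * (1 - case_fraction)
  }
  1 / sqrt(denom)
}

#' Simulate paired two-sample GWAS summary statistics
#'
#' Draws per-SNP exposure effects gamma from the scenario's Normal
#' distribution and direct effects alpha with the requested mean, sd and
#' correlation with gamma, then generates observed summary statistics:
#' `beta_exposure ~ N(gamma, se_exposure)` and `beta_outcome ~ N(theta *
#' gamma + alpha, se_outcome)`. Exposure standard errors are calibrated so a
#' typical draw clears genome-wide significance (`se = |gamma| *
#' sqrt(n_ref/n_exposure) / (1.5 * z_gw)` with `z_gw` the two-sided 5e-8
#' quantile and `n_ref = n_exposure` by default); outcome standard errors use
#' the standard allele-frequency-dependent GWAS approximation
#' `1/sqrt(2 p (1-p) N K (1-K))` (binary) or `1/sqrt(2 p (1-p) N)`
#' (continuous), with `eaf ~ Uniform(0.05, 0.95)`. Alleles are drawn from
#' non-palindromic pairs except for the requested palindromic fraction, and
#' the requested number of variants is deleted from the outcome table.
#'
#' @param scenario An [mr_scenario()].
#' @param n_ref Reference sample size for the exposure-se calibration.
#' @return List: `exposure` (an `mr_instruments` set selected at 5e-8),
#'   `outcome` (variant-association table) and `truth` (theta, gamma, alpha,
#'   eaf, palindromic flags, missing rsids, seed).
#' @export
simulate_two_sample <- function(scenario, n_ref = scenario$n_exposure) {
  s <- scenario
  stopifnot(inherits(s, "mr_scenario"))
  set.seed(s$seed)
  J <- s$n_snps

  z <- rnorm(J)
  gamma <- s$gamma_mean + s$gamma_sd * z
  alpha <- s$pleiotropy_mean + s$pleiotropy_sd *
    (s$inside_rho * z + sqrt(1 - s$inside_rho^2) * rnorm(J))

  z_gw <- qnorm(2.5e-8, lower.tail = FALSE)
  se_x <- pmax(abs(gamma), 1e-6) * sqrt(n_ref / s$n_exposure) / (1.5 * z_gw)
  eaf <- runif(J, 0.05, 0.95)
  se_y <- outcome_se(eaf, s$n_outcome, s$case_fraction)

  bx <- rnorm(J, gamma, se_x)
  by <- rnorm(J, s$theta * gamma + alpha, se_y)

  n_pal <- round(s$palindromic_fraction * J)
  pal <- seq_len(J) <= n_pal   # deterministic assignment given the draw order
  all_idx <- integer(J)
  all_idx[pal] <- sample.int(nrow(PALINDROMIC_PAIRS), n_pal, replace = TRUE)
  all_idx[!pal] <- sample.int(nrow(NON_PALINDROMIC_PAIRS), J - n_pal,
                              replace = TRUE)
  ea <- ifelse(pal, PALINDROMIC_PAIRS[all_idx, 1], NON_PALINDROMIC_PAIRS[all_idx, 1])
  oa <- ifelse(pal, PALINDROMIC_PAIRS[all_idx, 2], NON_PALINDROMIC_PAIRS[all_idx, 2])

  rsid <- sprintf("rs%07d", seq_len(J))
  exposure <- data.frame(
    rsid = rsid, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = bx, se = se_x, pvalue = 2 * pnorm(-abs(bx) / se_x),
    stringsAsFactors = FALSE)
  outcome <- data.frame(
    rsid = rsid, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = by, se = se_y, pvalue = 2 * pnorm(-abs(by) / se_y),
    stringsAsFactors = FALSE)
  missing_rsid <- character(0)
  if (s$missing_in_outcome > 0L) {
    drop <- sample.int(J, s$missing_in_outcome)
    missing_rsid <- rsid[drop]
    outcome <- outcome[-drop, , drop = FALSE]
  }

  set <- suppressWarnings(select_instruments(
    exposure, p_threshold = 5e-8, exposure_name = "synthetic exposure",
    sample_size = s$n_exposure))
  list(exposure = set, outcome = outcome,
       truth = list(theta = s$theta, gamma = gamma, alpha = alpha, eaf = eaf,
                    se_exposure = se_x, se_outcome = se_y,
                    palindromic = pal, missing_rsid = missing_rsid,
                    seed = s$seed))
}

#' Estimator-recovery experiment on synthetic data
#'
#' Repeats simulate -> harmonize -> estimate `n_reps` times (replicate seeds
#' derived deterministically from the scenario seed) and summarises each
#' estimator's bias, empirical and mean estimated standard error, and 95%
#' confidence-interval coverage of the true effect, together with the
#' rejection rates of the Egger intercept test and Cochran's Q at the 5%
#' level. Replicates where an estimator fails are counted, not fatal.
#'
#' @param scenario An [mr_scenario()].
#' @param n_reps Number of replicates (at least 2).
#' @param estimators Subset of `c("ivw", "egger", "weighted_median")`.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @return List: `estimates` (per-estimator summary data frame), `tests`
#'   (rejection rates and mean Egger intercept), `n_reps`.
#' @export
recovery_experiment <- function(scenario, n_reps,
                                estimators = c("ivw", "egger",
                                               "weighted_median"),
                                n_boot = 200) {
  stopifnot(n_reps >= 2)
  estimators <- match.arg(estimators, several.ok = TRUE)
  res <- list()
  egger_int <- numeric(0); egger_int_p <- numeric(0); q_p <- numeric(0)
  n_fail <- setNames(integer(length(estimators)), estimators)

  for (r in seq_len(n_reps)) {
    s <- scenario
    s$seed <- (scenario$seed + 104729L * r) %% .Machine$integer.max
    sim <- simulate_two_sample(s)
    h <- suppressMessages(harmonize(sim$exposure, sim$outcome))
    for (m in estimators) {
      est <- tryCatch(switch(m,
        ivw = mr_ivw(h),
        egger = mr_egger(h),
        weighted_median = mr_weighted_median(h, n_boot = n_boot,
                                             seed = s$seed)),
        mr_error = function(e) NULL, error = function(e) NULL)
      if (is.null(est)) { n_fail[m] <- n_fail[m] + 1L; next }
      if (m == "egger") {
        egger_int <- c(egger_int, est$intercept$estimate)
        egger_int_p <- c(egger_int_p, est$intercept$pvalue)
        est <- est$slope
      }
      res[[m]] <- rbind(res[[m]],
                        c(estimate = est$estimate, se = est$se))
    }
    qq <- tryCatch(cochran_q(h, "egger"), mr_error = function(e) NULL,
                   error = function(e) NULL)
    if (!is.null(qq)) q_p <- c(q_p, qq$pvalue)
  }

  theta <- scenario$theta
  z975 <- qnorm(0.975)
  summaries <- lapply(estimators, function(m) {
    x <- res[[m]]
    if (is.null(x)) {
      return(data.frame(method = m, n_ok = 0L, bias = NA_real_,
                        empirical_se = NA_real_, mean_se = NA_real_,
                        coverage = NA_real_, n_failed = n_fail[[m]]))
    }
    cover <- mean(abs(x[, "estimate"] - theta) <= z975 * x[, "se"])
    data.frame(method = m, n_ok = nrow(x),
               bias = mean(x[, "estimate"]) - theta,
               empirical_se = sd(x[, "estimate"]),
               mean_se = mean(x[, "se"]),
               coverage = cover, n_failed = n_fail[[m]],
               stringsAsFactors = FALSE)
  })
  tests <- data.frame(
    test = c("egger_intercept", "cochran_q_egger"),
    mean_value = c(if (length(egger_int)) mean(egger_int) else NA_real_,
                   NA_real_),
    rejection_rate = c(
      if (length(egger_int_p)) mean(egger_int_p < 0.05) else NA_real_,
      if (length(q_p)) mean(q_p < 0.05) else NA_real_),
    stringsAsFactors = FALSE)
  list(estimates = do.call(rbind, summaries), tests = tests, n_reps = n_reps)
}
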