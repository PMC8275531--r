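# Causal estimators over harmonized instruments: Wald ratio, IVW, MR-Egger,
# weighted median, mode-based. All operate on the included rows only and on
# the log-odds scale for binary traits.

new_mr_estimate <- function(method, estimate, se, pvalue, df, n_snps,
                            extras = list()) {
  structure(list(method = method, estimate = estimate, se = se,
                 pvalue = pvalue, df = df, n_snps = n_snps, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  dfl <- if (is.finite(x$df)) sprintf("t, df = %d", x$df) else "normal"
  cat(sprintf("%s (%d SNPs): estimate %.4g, se %.4g, p = %.4g [%s]\n",
              x$method, x$n_snps, x$estimate, x$se, x$pvalue, dfl))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             pvalue = x$pvalue, n_snps = x$n_snps, stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio estimates
#'
#' The ratio estimate for instrument j is `beta_outcome / beta_exposure` with
#' first-order standard error `se_outcome / |beta_exposure|`; a second-order
#' option adds the exposure uncertainty term
#' `beta_outcome^2 * se_exposure^2 / beta_exposure^4` under the square root.
#' P-values are two-sided normal.
#'
#' @param h Harmonized instrument table ([harmonize()]).
#' @param second_order Use the second-order delta-method standard error.
#' @return Data frame with one row per included instrument: `rsid`,
#'   `estimate`, `se`, `pvalue`.
#' @export
mr_wald_ratio <- function(h, second_order = FALSE) {
  d <- mr_inputs(h)
  if (nrow(d) < 1L) insufficient_instruments("Wald ratio", 1L, nrow(d))
  if (any(d$beta_exposure == 0)) {
    mr_error("Wald ratio undefined for beta_exposure = 0", "mr_domain_error")
  }
  est <- d$beta_outcome / d$beta_exposure
  se <- d$se_outcome / abs(d$beta_exposure)
  if (second_order) {
    se <- sqrt(d$se_outcome^2 / d$beta_exposure^2 +
                 d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4)
  }
  data.frame(rsid = d$rsid, estimate = est, se = se,
             pvalue = 2 * pnorm(-abs(est) / se), stringsAsFactors = FALSE)
}

# closed-form weighted regression through the origin with weights 1/se_out^2
ivw_point <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(w * bx * by) / sum(w * bx^2)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of the outcome effects on the exposure effects through
#' the origin, weights `1/se_outcome^2` — the inverse-variance-weighted
#' meta-analysis of the Wald ratios. Under the default multiplicative
#' random-effects model the fixed-effect standard error is inflated by
#' `max(1, sqrt(Q/(J-1)))`, so it is never deflated below the fixed-effect
#' value in underdispersed data. P-values are two-sided normal.
#'
#' @param h Harmonized instrument table.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_estimate`; `extras` carries the fixed-effect se, the
#'   heterogeneity statistic `Q` and the se multiplier.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- mr_inputs(h)
  J <- nrow(d)
  if (J < 2L) insufficient_instruments("IVW", 2L, J)
  w <- 1 / d$se_outcome^2
  theta <- ivw_point(d$beta_exposure, d$beta_outcome, d$se_outcome)
  se_fixed <- sqrt(1 / sum(w * d$beta_exposure^2))
  Q <- sum(w * (d$beta_outcome - theta * d$beta_exposure)^2)
  mult <- if (model == "random") max(1, sqrt(Q / (J - 1))) else 1
  se <- se_fixed * mult
  new_mr_estimate(
    method = if (model == "random") "Inverse variance weighted" else "IVW (fixed)",
    estimate = theta, se = se, pvalue = 2 * pnorm(-abs(theta) / se),
    df = Inf, n_snps = J,
    extras = list(se_fixed = se_fixed, Q = Q, multiplier = mult))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with an
#' intercept, weights `1/se_outcome^2`, after orienting every instrument to a
#' positive exposure effect. The intercept estimates the average directional
#' pleiotropy; the slope is the pleiotropy-adjusted causal effect. Standard
#' errors use the residual scale `sqrt(Q/(J-2))` floored at 1, and p-values
#' are two-sided t with J - 2 degrees of freedom.
#'
#' @param h Harmonized instrument table.
#' @return List of class `mr_egger_fit`: `slope` (an `mr_estimate`),
#'   `intercept` (estimate, se, pvalue, df), and the heterogeneity statistic
#'   `Q` with its degrees of freedom.
#' @export
mr_egger <- function(h) {
  d <- mr_inputs(h)
  J <- nrow(d)
  if (J < 3L) insufficient_instruments("MR-Egger", 3L, J)
  s <- ifelse(d$beta_exposure < 0, -1, 1)
  bx <- d$beta_exposure * s
  by <- d$beta_outcome * s
  w <- 1 / d$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  Q <- sum(w * residuals(fit)^2)
  scale <- sqrt(Q / (J - 2))
  infl <- max(1, scale) / scale   # floor the residual sd at 1
  se <- cf[, "Std. Error"] * infl
  pv <- 2 * pt(-abs(cf[, "Estimate"] / se), df = J - 2)
  slope <- new_mr_estimate("MR Egger", unname(cf["bx", "Estimate"]),
                           unname(se["bx"]), unname(pv["bx"]),
                           df = J - 2, n_snps = J,
                           extras = list(residual_scale = scale))
  intercept <- list(estimate = unname(cf["(Intercept)", "Estimate"]),
                    se = unname(se["(Intercept)"]),
                    pvalue = unname(pv["(Intercept)"]),
                    df = J - 2)
  structure(list(slope = slope, intercept = intercept, Q = Q, Q_df = J - 2),
            class = "mr_egger_fit")
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4g, se %.4g, p = %.4g (t, df = %d)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue,
              x$intercept$df))
  invisible(x)
}

# the weighted-median point estimate on ratio estimates th with weights w
weighted_median_point <- function(th, w) {
  o <- order(th)
  th <- th[o]; w <- w[o]
  if (sum(w) <= 0) mr_error("degenerate (zero) weights", "mr_domain_error")
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1L]) return(th[1L])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  approx(s, th, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap over instrument-level Gaussian error
bootstrap_se <- function(d, point_fun, n_boot, seed) {
  J <- nrow(d)
  est <- numeric(n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    bx <- d$beta_exposure + rnorm(J, 0, d$se_exposure)
    by <- d$beta_outcome + rnorm(J, 0, d$se_outcome)
    est[b] <- point_fun(bx, by)
  }
  sd(est)
}

#' Weighted median estimate
#'
#' The weighted median of the per-SNP ratio estimates, with inverse-variance
#' weights `(beta_exposure/se_outcome)^2`: consistent when instruments
#' carrying at least half the weight are valid. The standard error is the
#' spread of the estimator over a seeded parametric bootstrap (each summary
#' effect perturbed by its Gaussian standard error); the p-value is two-sided
#' normal.
#'
#' @param h Harmonized instrument table.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  d <- mr_inputs(h)
  J <- nrow(d)
  if (J < 3L) insufficient_instruments("weighted median", 3L, J)
  stopifnot(n_boot >= 1)
  point <- function(bx, by) {
    weighted_median_point(by / bx, (bx / d$se_outcome)^2)
  }
  theta <- point(d$beta_exposure, d$beta_outcome)
  se <- bootstrap_se(d, point, n_boot, seed)
  new_mr_estimate("Weighted median", theta, se,
                  2 * pnorm(-abs(theta) / se), df = Inf, n_snps = J,
                  extras = list(n_boot = n_boot, seed = seed))
}

# kernel-mode of ratio estimates; weights must sum to 1
mode_point <- function(th, w, phi, grid_n = 512L) {
  spread <- min(sd(th), mad(th))
  bw <- phi * 0.9 * spread * length(th)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) {
    return(list(mode = th[which.max(w)], bandwidth = 0))
  }
  grid <- seq(min(th) - 3 * bw, max(th) + 3 * bw, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - th) / bw)), numeric(1))
  list(mode = grid[which.max(dens)], bandwidth = bw)
}

#' Mode-based estimate
#'
#' The mode of a Gaussian-kernel density over the per-SNP ratio estimates:
#' consistent when the largest homogeneous subset of instruments is valid,
#' even if that subset is a minority. `weighted = TRUE` ("weighted mode")
#' weights the kernel by `(beta_exposure/se_outcome)^2` normalized to one;
#' `weighted = FALSE` ("simple mode") weights uniformly. The bandwidth is the
#' modified Silverman rule `phi * 0.9 * min(sd, mad) * J^(-1/5)`; the mode is
#' read off a 512-point grid spanning the ratio range plus three bandwidths.
#' Standard error by seeded parametric bootstrap; p-value two-sided normal.
#'
#' @param h Harmonized instrument table.
#' @param weighted Weight the density by instrument precision.
#' @param phi Bandwidth inflation factor (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return An `mr_estimate`; `extras` records `phi`, the realized bandwidth
#'   and the grid resolution.
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = 1) {
  d <- mr_inputs(h)
  J <- nrow(d)
  if (J < 3L) insufficient_instruments("mode-based estimate", 3L, J)
  stopifnot(phi > 0, n_boot >= 1)
  point <- function(bx, by) {
    th <- by / bx
    w <- if (weighted) (bx / d$se_outcome)^2 else rep(1, J)
    mode_point(th, w / sum(w), phi)$mode
  }
  th0 <- d$beta_outcome / d$beta_exposure
  w0 <- if (weighted) (d$beta_exposure / d$se_outcome)^2 else rep(1, J)
  fit <- mode_point(th0, w0 / sum(w0), phi)
  se <- bootstrap_se(d, point, n_boot, seed)
  new_mr_estimate(if (weighted) "Weighted mode" else "Simple mode",
                  fit$mode, se, 2 * pnorm(-abs(fit$mode) / se),
                  df = Inf, n_snps = J,
                  extras = list(phi = phi, bandwidth = fit$bandwidth,
                                grid_n = 512L, n_boot = n_boot, seed = seed))
}

#' All multi-SNP estimates as one table
#'
#' Convenience wrapper running IVW, MR-Egger, weighted median, simple mode and
#' weighted mode on the same harmonized set, mirroring the layout of a
#' published MR results table. Methods whose instrument minimum is not met
#' are reported as not run rather than aborting the table.
#'
#' @param h Harmonized instrument table.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Seed for all resampling.
#' @return Data frame with columns `method`, `estimate`, `se`, `pvalue`,
#'   `n_snps`, `note`.
#' @export
mr_all_estimates <- function(h, n_boot = 1000, seed = 1) {
  runs <- list(
    function() mr_ivw(h),
    function() mr_egger(h)$slope,
    function() mr_weighted_median(h, n_boot = n_boot, seed = seed),
    function() mr_mode(h, weighted = FALSE, n_boot = n_boot, seed = seed),
    function() mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seed))
  names(runs) <- c("Inverse variance weighted", "MR Egger", "Weighted median",
                   "Simple mode", "Weighted mode")
  rows <- lapply(names(runs), function(m) {
    res <- tryCatch(runs[[m]](), mr_insufficient_instruments = function(e) e)
    if (inherits(res, "mr_estimate")) {
      cbind(as.data.frame(res), note = "")
    } else {
      data.frame(method = m, estimate = NA_real_, se = NA_real_,
                 pvalue = NA_real_, n_snps = nrow(included(h)),
                 note = "not run: insufficient instruments",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
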