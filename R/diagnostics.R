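# Instrument-strength, heterogeneity, influence and plot-data diagnostics.

#' Multi-instrument F-statistic for instrument strength
#'
#' `F = (r2 / (1 - r2)) * (n - k - 1) / k` for an instrument explaining a
#' fraction `r2` of the exposure variance in a GWAS of `n` individuals with
#' `k` variants. Values below 10 conventionally flag a weak instrument.
#'
#' @param r2 Variance explained, in (0, 1).
#' @param n Exposure-GWAS sample size.
#' @param k Number of instruments.
#' @return The F-statistic.
#' @examples
#' f_statistic(0.0284, 79366, 6)
#' @export
f_statistic <- function(r2, n, k) {
  if (!is.numeric(r2) || r2 <= 0 || r2 >= 1) {
    mr_error("r2 must lie strictly in (0, 1)", "mr_domain_error")
  }
  if (n <= k + 1 || k < 1) {
    mr_error("need n > k + 1 >= 2", "mr_domain_error")
  }
  (r2 / (1 - r2)) * (n - k - 1) / k
}

#' Cochran's Q heterogeneity statistic
#'
#' The weighted residual sum of squares of the fitted IVW (no intercept,
#' df = J - 1) or Egger (with intercept, df = J - 2) regression, weights
#' `1/se_outcome^2`, referred to the upper tail of the chi-square
#' distribution. Excess heterogeneity indicates that the per-SNP causal
#' estimates are not mutually consistent.
#'
#' @param h Harmonized instrument table.
#' @param model `"ivw"` or `"egger"`.
#' @return List of class `mr_heterogeneity`: `model`, `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, model = c("ivw", "egger")) {
  model <- match.arg(model)
  d <- mr_inputs(h)
  J <- nrow(d)
  if (model == "ivw") {
    if (J < 2L) insufficient_instruments("Cochran's Q (IVW)", 2L, J)
    Q <- mr_ivw(h)$extras$Q
    df <- J - 1L
  } else {
    if (J < 3L) insufficient_instruments("Cochran's Q (Egger)", 3L, J)
    fit <- mr_egger(h)
    Q <- fit$Q
    df <- J - 2L
  }
  structure(list(model = model, Q = Q, df = df,
                 pvalue = pchisq(Q, df, lower.tail = FALSE)),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s, df = %d) = %.3f, p = %.4g\n",
              x$model, x$df, x$Q, x$pvalue))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-fits the default IVW estimator (multiplicative random effects with the
#' fixed-effect floor) dropping each included instrument in turn, to expose
#' single variants that drive the pooled estimate. Both the floored
#' random-effects and the fixed-effect standard errors are reported.
#'
#' @param h Harmonized instrument table (at least 3 included instruments).
#' @return Data frame with columns `dropped_rsid`, `estimate`, `se`,
#'   `se_fixed`, `pvalue`, `n_snps`.
#' @export
leave_one_out <- function(h) {
  d <- mr_inputs(h)
  J <- nrow(d)
  if (J < 3L) insufficient_instruments("leave-one-out", 3L, J)
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(d[-j, , drop = FALSE])
    data.frame(dropped_rsid = d$rsid[j], estimate = est$estimate,
               se = est$se, se_fixed = est$extras$se_fixed,
               pvalue = est$pvalue, n_snps = est$n_snps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forest-plot table of single-SNP and method estimates
#'
#' Wald ratios for every included instrument (input order) followed by each
#' multi-SNP estimate as a summary row.
#'
#' @param h Harmonized instrument table.
#' @param n_boot,seed Passed to the resampling estimators.
#' @return Data frame with columns `label`, `type` (`"snp"`/`"method"`),
#'   `estimate`, `se`, `pvalue`. Empty (zero rows) for an empty set.
#' @export
single_snp_table <- function(h, n_boot = 1000, seed = 1) {
  d <- included(h)
  empty <- data.frame(label = character(), type = character(),
                      estimate = numeric(), se = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(empty)
  w <- mr_wald_ratio(h)
  snp <- data.frame(label = w$rsid, type = "snp", estimate = w$estimate,
                    se = w$se, pvalue = w$pvalue, stringsAsFactors = FALSE)
  meth <- mr_all_estimates(h, n_boot = n_boot, seed = seed)
  meth <- meth[is.na(meth$estimate) | meth$note == "", , drop = FALSE]
  meth <- meth[!is.na(meth$estimate), , drop = FALSE]
  if (nrow(meth)) {
    meth <- data.frame(label = meth$method, type = "method",
                       estimate = meth$estimate, se = meth$se,
                       pvalue = meth$pvalue, stringsAsFactors = FALSE)
  } else meth <- empty
  out <- rbind(snp, meth)
  rownames(out) <- NULL
  out
}

#' Funnel-plot data
#'
#' Per-SNP ratio estimates against their precision `|beta_exposure| /
#' se_outcome` (the reciprocal first-order ratio standard error). Asymmetry
#' about the pooled estimate suggests directional pleiotropy.
#'
#' @param h Harmonized instrument table.
#' @return Data frame with columns `rsid`, `ratio_estimate`, `precision`.
#' @export
funnel_data <- function(h) {
  d <- included(h)
  if (nrow(d) == 0L) {
    return(data.frame(rsid = character(), ratio_estimate = numeric(),
                      precision = numeric(), stringsAsFactors = FALSE))
  }
  w <- mr_wald_ratio(h)
  data.frame(rsid = w$rsid, ratio_estimate = w$estimate,
             precision = abs(d$beta_exposure) / d$se_outcome,
             stringsAsFactors = FALSE)
}

#' Scatter-plot data with fitted method lines
#'
#' Per-SNP exposure and outcome effects with standard errors, plus an
#' intercept/slope line per multi-SNP method (zero intercept except
#' MR-Egger).
#'
#' @param h Harmonized instrument table.
#' @param n_boot,seed Passed to the resampling estimators.
#' @return Data frame of points (`rsid`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`); fitted lines in attribute `lines`
#'   (`method`, `intercept`, `slope`).
#' @export
scatter_data <- function(h, n_boot = 1000, seed = 1) {
  d <- included(h)
  pts <- d[, c("rsid", "beta_exposure", "se_exposure",
               "beta_outcome", "se_outcome"), drop = FALSE]
  rownames(pts) <- NULL
  lines <- data.frame(method = character(), intercept = numeric(),
                      slope = numeric(), stringsAsFactors = FALSE)
  if (nrow(d) > 0L) {
    est <- mr_all_estimates(h, n_boot = n_boot, seed = seed)
    est <- est[!is.na(est$estimate), , drop = FALSE]
    if (nrow(est)) {
      icpt <- rep(0, nrow(est))
      if ("MR Egger" %in% est$method) {
        icpt[est$method == "MR Egger"] <- mr_egger(h)$intercept$estimate
      }
      lines <- data.frame(method = est$method, intercept = icpt,
                          slope = est$estimate, stringsAsFactors = FALSE)
    }
  }
  structure(pts, lines = lines)
}
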