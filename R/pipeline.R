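# Orchestration: full bidirectional-capable analysis over harmonized
# instruments, config-driven runs, and TSV/JSON report output.

#' Run a complete two-sample MR analysis
#'
#' Executes harmonization, all causal estimators, the pleiotropy /
#' heterogeneity / outlier / influence diagnostics, and (when the outcome is
#' binary with known case counts) the power analysis, on one
#' exposure-outcome direction. Estimators whose instrument minimum is not met
#' are reported as not run; the analysis continues.
#'
#' @param exposure An `mr_instruments` set (see [select_instruments()],
#'   [mr_fixture()]).
#' @param outcome Variant-association table of the outcome study.
#' @param policy,eaf_threshold Passed to [harmonize()].
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param n_sim MR-PRESSO simulation replicates.
#' @param seed Seed for all resampling.
#' @param n_outcome,case_fraction Outcome-study size and case fraction for
#'   the power analysis (`NULL` skips it).
#' @param metadata Optional named list stored in the report provenance.
#' @return List of class `mr_report`: `harmonization`, `estimates`,
#'   `single_snp`, `pleiotropy`, `heterogeneity`, `presso`, `leave_one_out`,
#'   `f_statistic`, `power`, `funnel`, `scatter`, `provenance`.
#' @export
mr_analyze <- function(exposure, outcome,
                       policy = "drop_all_palindromic", eaf_threshold = 0.42,
                       n_boot = 1000, n_sim = 1000, seed = 1,
                       n_outcome = NULL, case_fraction = NULL,
                       metadata = list()) {
  h <- harmonize(exposure, outcome, policy = policy,
                 eaf_threshold = eaf_threshold)
  J <- nrow(included(h))

  try_mr <- function(f) tryCatch(f(), mr_error = function(e) {
    structure(list(message = conditionMessage(e)), class = "mr_not_run")
  })

  estimates <- mr_all_estimates(h, n_boot = n_boot, seed = seed)
  egger <- try_mr(function() mr_egger(h))
  pleiotropy <- if (inherits(egger, "mr_egger_fit")) egger$intercept else egger
  het <- list(ivw = try_mr(function() cochran_q(h, "ivw")),
              egger = try_mr(function() cochran_q(h, "egger")))
  presso <- try_mr(function() mr_presso(h, n_sim = n_sim, seed = seed))
  loo <- try_mr(function() leave_one_out(h))
  single <- try_mr(function() mr_wald_ratio(h))

  r2 <- attr(exposure, "variance_explained")
  n_exp <- attr(exposure, "sample_size")
  fstat <- NULL
  if (!is.null(r2) && !is.na(r2) && !is.null(n_exp) && !is.na(n_exp)) {
    fstat <- f_statistic(r2, n_exp, nrow(exposure))
  }
  power <- NULL
  if (!is.null(n_outcome) && !is.null(case_fraction) &&
      !is.null(r2) && !is.na(r2)) {
    power <- list(
      n_outcome = n_outcome, case_fraction = case_fraction, r2 = r2,
      alpha = 0.05,
      detectable_or_80 = mr_detectable_or(0.80, n_outcome, case_fraction, r2),
      power_at_or_1.27 = mr_power_binary(1.27, n_outcome, case_fraction, r2))
  }

  structure(list(
    harmonization = as.data.frame(h),
    estimates = estimates,
    single_snp = single,
    pleiotropy = pleiotropy,
    heterogeneity = het,
    presso = presso,
    leave_one_out = loo,
    f_statistic = fstat,
    power = power,
    funnel = funnel_data(h),
    scatter = scatter_data(h, n_boot = n_boot, seed = seed),
    provenance = c(list(
      package_version = as.character(packageVersion("mrkit")),
      seed = seed, n_boot = n_boot, n_sim = n_sim, policy = policy,
      n_included = J), metadata)),
    class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  st <- table(x$harmonization$status)
  cat("Two-sample MR analysis:", x$provenance$n_included,
      "included instruments\n")
  cat("  harmonization:",
      paste(names(st), unname(st), sep = " = ", collapse = ", "), "\n")
  print(x$estimates, digits = 3)
  invisible(x)
}

# serialise report pieces (drop closures/conditions, keep numbers)
report_json_payload <- function(report) {
  scrub <- function(x) {
    if (inherits(x, "mr_not_run")) return(list(not_run = x$message))
    if (inherits(x, "mr_estimate")) return(unclass(x))
    if (inherits(x, c("mr_heterogeneity", "mr_presso_fit", "mr_egger_fit"))) {
      return(lapply(unclass(x), scrub))
    }
    if (is.data.frame(x)) { attr(x, "lines") <- NULL; return(x) }
    if (is.list(x)) return(lapply(x, scrub))
    x
  }
  lapply(unclass(report), scrub)
}

fmt3 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 3))

#' Write an analysis report to disk
#'
#' Emits `estimates.tsv` (method table, three decimals, mirroring the layout
#' of a published MR results table), `harmonization.tsv`, `single_snp.tsv`,
#' `heterogeneity.tsv`, `loo.tsv`, `forest.tsv`, `funnel.tsv`, `scatter.tsv`
#' (full precision) and `report.json` (full precision). Output is
#' deterministic for a fixed config and seed; no timestamps are written.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  est <- report$estimates
  est3 <- data.frame(method = est$method, beta = fmt3(est$estimate),
                     se = fmt3(est$se), pvalue = fmt3(est$pvalue),
                     n_snps = est$n_snps, note = est$note)
  paths <- c(
    tsv(est3, "estimates.tsv"),
    tsv(report$harmonization, "harmonization.tsv"),
    tsv(report$funnel, "funnel.tsv"))
  if (is.data.frame(report$single_snp)) {
    paths <- c(paths, tsv(report$single_snp, "single_snp.tsv"))
  }
  if (is.data.frame(report$leave_one_out)) {
    paths <- c(paths, tsv(report$leave_one_out, "loo.tsv"))
  }
  het <- report$heterogeneity
  hrows <- lapply(names(het), function(m) {
    x <- het[[m]]
    if (inherits(x, "mr_heterogeneity")) {
      data.frame(model = x$model, Q = x$Q, df = x$df, pvalue = x$pvalue)
    } else NULL
  })
  hrows <- do.call(rbind, hrows)
  if (!is.null(hrows)) paths <- c(paths, tsv(hrows, "heterogeneity.tsv"))
  sc <- report$scatter
  if (is.data.frame(sc)) {
    paths <- c(paths, tsv(as.data.frame(sc), "scatter.tsv"))
    ln <- attr(sc, "lines")
    if (is.data.frame(ln) && nrow(ln)) paths <- c(paths, tsv(ln, "scatter_lines.tsv"))
  }
  forest <- tryCatch(
    rbind(data.frame(label = report$single_snp$rsid, type = "snp",
                     estimate = report$single_snp$estimate,
                     se = report$single_snp$se,
                     pvalue = report$single_snp$pvalue),
          data.frame(label = est$method[!is.na(est$estimate)], type = "method",
                     estimate = est$estimate[!is.na(est$estimate)],
                     se = est$se[!is.na(est$estimate)],
                     pvalue = est$pvalue[!is.na(est$estimate)])),
    error = function(e) NULL)
  if (!is.null(forest)) paths <- c(paths, tsv(forest, "forest.tsv"))

  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report_json_payload(report), jp, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(c(paths, jp))
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      mr_error("yaml package required for YAML configs; use JSON instead",
               "mr_config_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run a config-driven analysis
#'
#' Reads a YAML or JSON configuration describing the exposure and outcome
#' summary-statistics files (paths plus column maps), optional LD proxy
#' table, harmonization policy, estimator settings and output directory;
#' executes select -> proxy-substitute -> harmonize -> estimate ->
#' diagnostics -> power; and writes the report artifacts.
#'
#' Config keys: `exposure` (`path`, `columns`, `name`, `n`, `r2`,
#' `p_threshold`), `outcome` (`path`, `columns`, `n`, `cases`),
#' `proxies` (optional path), `policy`, `seed`, `n_boot`, `n_sim`,
#' `output_dir`.
#'
#' @param config Path to a YAML/JSON file, or an equivalent named list.
#' @return The `mr_report`, invisibly.
#' @export
run_analysis <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  for (k in c("exposure", "outcome")) {
    if (is.null(cfg[[k]]) || is.null(cfg[[k]]$path) || is.null(cfg[[k]]$columns)) {
      mr_error(paste0("config must provide ", k, "$path and ", k, "$columns"),
               "mr_config_error")
    }
  }
  ex_raw <- read_summary_stats(cfg$exposure$path, cfg$exposure$columns)
  ou <- read_summary_stats(cfg$outcome$path, cfg$outcome$columns)
  exposure <- select_instruments(
    ex_raw,
    p_threshold = cfg$exposure$p_threshold %||% 5e-8,
    exposure_name = cfg$exposure$name %||% "exposure",
    variance_explained = cfg$exposure$r2 %||% NA_real_,
    sample_size = cfg$exposure$n %||% NA_integer_)
  if (!is.null(cfg$proxies)) {
    ptab <- read.delim(cfg$proxies, stringsAsFactors = FALSE)
    exposure <- substitute_proxies(exposure, ou$rsid, ptab, ex_raw)
  }
  case_fraction <- NULL
  if (!is.null(cfg$outcome$cases) && !is.null(cfg$outcome$n)) {
    case_fraction <- cfg$outcome$cases / cfg$outcome$n
  }
  report <- mr_analyze(
    exposure, ou,
    policy = cfg$policy %||% "drop_all_palindromic",
    n_boot = cfg$n_boot %||% 1000,
    n_sim = cfg$n_sim %||% 1000,
    seed = cfg$seed %||% 1,
    n_outcome = cfg$outcome$n,
    case_fraction = case_fraction,
    metadata = list(exposure_name = cfg$exposure$name %||% "exposure"))
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  invisible(report)
}
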