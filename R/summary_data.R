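# Summary-statistics data model: variant associations, instrument sets,
# proxy substitution and allele harmonization.

VALID_STATUS <- c("included", "proxy_substituted", "excluded_palindromic",
                  "excluded_missing", "excluded_conflict")

#' Convert an odds ratio to a log-odds effect size
#'
#' Binary-trait GWAS commonly report per-allele odds ratios; all MR arithmetic
#' operates on the log-odds scale, so odds ratios are converted with the
#' natural logarithm.
#'
#' @param odds_ratio Positive odds ratio(s).
#' @return `log(odds_ratio)`.
#' @examples
#' or_to_beta(1.0313)
#' @export
or_to_beta <- function(odds_ratio) {
  if (!is.numeric(odds_ratio) || any(!is.finite(odds_ratio)) ||
      any(odds_ratio <= 0)) {
    mr_error("odds_ratio must be a positive finite number", "mr_domain_error")
  }
  log(odds_ratio)
}

#' Is an allele pair palindromic?
#'
#' A biallelic SNP is palindromic when its two alleles are reverse complements
#' of each other (A/T or C/G), so the strand cannot be resolved from the
#' alleles alone. Indel alleles are never classified palindromic: strand logic
#' is undefined for them, and a note is emitted.
#'
#' @param a1,a2 Allele strings (vectorised).
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")
#' is_palindromic("A", "G")
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  snv <- nchar(a1) == 1L & nchar(a2) == 1L &
    a1 %in% c("A", "C", "G", "T") & a2 %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    message("is_palindromic: indel or non-ACGT alleles classified FALSE (",
            sum(!snv), " pair(s))")
  }
  out <- rep(FALSE, length(a1))
  out[snv] <- (a1[snv] == "A" & a2[snv] == "T") |
    (a1[snv] == "T" & a2[snv] == "A") |
    (a1[snv] == "C" & a2[snv] == "G") |
    (a1[snv] == "G" & a2[snv] == "C")
  out
}

complement_allele <- function(a) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(a %in% names(map), unname(map[a]), NA_character_)
}

# validate a variant-association table and normalise its columns
validate_associations <- function(x, require_eaf = FALSE) {
  needed <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    mr_error(paste("missing association columns:", paste(miss, collapse = ", ")),
             "mr_schema_error")
  }
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"proxy_of" %in% names(x)) x$proxy_of <- NA_character_
  x$proxy_of[x$proxy_of %in% c(".", "")] <- NA_character_
  bad <- !is.na(x$beta) & (!is.finite(x$se) | x$se <= 0)
  if (any(bad)) mr_error("standard errors must be > 0", "mr_domain_error")
  if (any(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))) {
    mr_error("eaf must lie in [0, 1]", "mr_domain_error")
  }
  # p-values of extremely strong hits can underflow to 0 in double precision
  if (any(!is.na(x$pvalue) & (x$pvalue < 0 | x$pvalue > 1))) {
    mr_error("p-values must lie in [0, 1]", "mr_domain_error")
  }
  if (any(x$effect_allele == x$other_allele)) {
    mr_error("effect_allele must differ from other_allele", "mr_domain_error")
  }
  x
}

#' Select genome-wide significant instruments
#'
#' Filters a variant-association table to the rows passing the significance
#' threshold and stamps the selection metadata (threshold, exposure name,
#' variance explained, sample size) on the returned set.
#'
#' @param associations Data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `eaf`, `proxy_of`.
#' @param p_threshold Selection threshold; variants with `pvalue < p_threshold`
#'   are retained (default genome-wide significance, 5e-8).
#' @param exposure_name Label for the exposure trait.
#' @param variance_explained Optional externally supplied instrument R-squared.
#' @param sample_size Optional exposure-GWAS sample size.
#' @return The filtered data frame of class `mr_instruments`, with the
#'   selection metadata in attributes `p_threshold`, `exposure_name`,
#'   `variance_explained` and `sample_size`.
#' @export
select_instruments <- function(associations, p_threshold = 5e-8,
                               exposure_name = "exposure",
                               variance_explained = NA_real_,
                               sample_size = NA_integer_) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    mr_error("p_threshold must lie in (0, 1]", "mr_domain_error")
  }
  x <- validate_associations(as.data.frame(associations))
  keep <- !is.na(x$pvalue) & x$pvalue < p_threshold
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$rsid)) {
    mr_error("instrument rsids must be unique", "mr_domain_error")
  }
  if (nrow(out) == 0L) {
    warning("no variants pass p < ", format(p_threshold),
            "; downstream estimators will refuse an empty set")
  }
  structure(out,
            class = c("mr_instruments", "data.frame"),
            p_threshold = p_threshold,
            exposure_name = exposure_name,
            variance_explained = variance_explained,
            sample_size = sample_size)
}

#' Pick the best LD proxy for a missing lead variant
#'
#' Candidates are first restricted to `r2 >= r2_min` (default 0.40), then
#' ranked lexicographically by the requested criteria: `"max_r2"` (higher
#' linkage first), `"min_abs_distance"` (closer to the lead first),
#' `"non_palindromic"` (non-palindromic alleles first). Remaining ties break
#' deterministically by proxy rsid.
#'
#' @param lead_rsid The missing lead variant.
#' @param candidates Data frame with columns `lead_rsid`, `proxy_rsid`, `r2`,
#'   `distance`, `a1`, `a2`.
#' @param criteria Character vector of ranking criteria, applied in order.
#' @param r2_min Minimum linkage disequilibrium r-squared.
#' @return One-row data frame (the chosen candidate, with a `palindromic`
#'   column added), or `NULL` when no candidate survives.
#' @export
select_proxy <- function(lead_rsid, candidates,
                         criteria = c("max_r2", "min_abs_distance"),
                         r2_min = 0.40) {
  stopifnot(is.character(lead_rsid), length(lead_rsid) == 1L)
  ok <- criteria %in% c("max_r2", "min_abs_distance", "non_palindromic")
  if (!all(ok)) {
    mr_error(paste("unknown proxy criteria:",
                   paste(criteria[!ok], collapse = ", ")), "mr_domain_error")
  }
  cc <- candidates[candidates$lead_rsid == lead_rsid & candidates$r2 >= r2_min, ,
                   drop = FALSE]
  if (nrow(cc) == 0L) return(NULL)
  if (any(cc$proxy_rsid == lead_rsid)) {
    mr_error("a proxy cannot be its own lead", "mr_domain_error")
  }
  if (!"palindromic" %in% names(cc)) {
    cc$palindromic <- suppressMessages(is_palindromic(cc$a1, cc$a2))
  }
  keys <- lapply(criteria, function(cr) {
    switch(cr,
           max_r2 = -cc$r2,
           min_abs_distance = abs(cc$distance),
           non_palindromic = as.integer(cc$palindromic))
  })
  ord <- do.call(order, c(keys, list(cc$proxy_rsid)))
  out <- cc[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Substitute LD proxies for instruments missing from the other study
#'
#' For each instrument whose rsid is absent from `available_rsids`, the best
#' proxy under [select_proxy()] is sought among `proxy_table`; if that proxy
#' has an association record in `proxy_associations` (its effect in the
#' exposure study), the instrument row is replaced by the proxy's record with
#' `proxy_of` set to the lead rsid. The proxy's effect is used as reported for
#' the proxy itself, not rescaled by r-squared. Leads with no usable proxy are
#' left in place for harmonization to flag as missing.
#'
#' @param instruments An `mr_instruments` set (see [select_instruments()]).
#' @param available_rsids Character vector of rsids present in the other study.
#' @param proxy_table LD table (`lead_rsid`, `proxy_rsid`, `r2`, `distance`,
#'   `a1`, `a2`).
#' @param proxy_associations Variant-association table holding the proxies'
#'   effects in the exposure study.
#' @inheritParams select_proxy
#' @return The instrument set with substitutions applied.
#' @export
substitute_proxies <- function(instruments, available_rsids, proxy_table,
                               proxy_associations,
                               criteria = c("max_r2", "min_abs_distance"),
                               r2_min = 0.40) {
  pa <- validate_associations(as.data.frame(proxy_associations))
  out <- instruments
  for (i in seq_len(nrow(out))) {
    lead <- out$rsid[i]
    if (lead %in% available_rsids) next
    best <- select_proxy(lead, proxy_table, criteria = criteria, r2_min = r2_min)
    if (is.null(best) || !(best$proxy_rsid %in% pa$rsid) ||
        !(best$proxy_rsid %in% available_rsids)) next
    rec <- pa[pa$rsid == best$proxy_rsid, , drop = FALSE][1L, ]
    for (col in intersect(names(out), names(rec))) out[i, col] <- rec[[col]]
    out$rsid[i] <- rec$rsid
    out$proxy_of[i] <- lead
  }
  out
}

#' Harmonize exposure and outcome associations onto a common effect allele
#'
#' Matches each exposure instrument to the outcome study by rsid, re-orients
#' the outcome effect onto the exposure's effect allele (allele swap negates
#' the outcome beta and complements its frequency; a strand flip complements
#' the outcome alleles before re-matching), and applies the palindromic-SNP
#' policy. Under `"drop_all_palindromic"` (the default) every palindromic
#' variant is excluded, since its strand cannot be verified. Under
#' `"keep_inferable_palindromic"` a palindromic variant is retained when its
#' minor-allele frequency is below `eaf_threshold` in both studies, and
#' orientation is inferred by frequency matching.
#'
#' @param exposure An `mr_instruments` set (or plain association table).
#' @param outcome Variant-association table of the outcome study.
#' @param policy Palindromic-variant policy.
#' @param eaf_threshold Ambiguity bound for the frequency-inference policy
#'   (default 0.42).
#' @return Data frame of class `mr_harmonized`, one row per exposure
#'   instrument in input order: `rsid`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `status`, `reason`, `proxy_of`. Estimators
#'   use rows with status `included` or `proxy_substituted`.
#' @export
harmonize <- function(exposure, outcome,
                      policy = c("drop_all_palindromic",
                                 "keep_inferable_palindromic"),
                      eaf_threshold = 0.42) {
  policy <- match.arg(policy)
  ex <- validate_associations(as.data.frame(exposure))
  ou <- validate_associations(as.data.frame(outcome))

  n <- nrow(ex)
  out <- data.frame(
    rsid = ex$rsid,
    effect_allele = toupper(ex$effect_allele),
    other_allele = toupper(ex$other_allele),
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    eaf_exposure = ex$eaf,
    beta_outcome = NA_real_,
    se_outcome = NA_real_,
    eaf_outcome = NA_real_,
    status = NA_character_,
    reason = NA_character_,
    proxy_of = ex$proxy_of,
    stringsAsFactors = FALSE
  )

  for (i in seq_len(n)) {
    ea <- out$effect_allele[i]; oa <- out$other_allele[i]
    j <- match(out$rsid[i], ou$rsid)
    if (is.na(j)) {
      out$status[i] <- "excluded_missing"
      out$reason[i] <- "absent from outcome study and no usable proxy"
      next
    }
    o_ea <- toupper(ou$effect_allele[j]); o_oa <- toupper(ou$other_allele[j])
    by <- ou$beta[j]; sy <- ou$se[j]; fy <- ou$eaf[j]

    flip <- NA  # TRUE: outcome beta negated relative to reported
    if (o_ea == ea && o_oa == oa) {
      flip <- FALSE
    } else if (o_ea == oa && o_oa == ea) {
      flip <- TRUE
    } else {
      c_ea <- complement_allele(o_ea); c_oa <- complement_allele(o_oa)
      if (!is.na(c_ea) && !is.na(c_oa)) {
        if (c_ea == ea && c_oa == oa) flip <- FALSE
        else if (c_ea == oa && c_oa == ea) flip <- TRUE
      }
    }
    if (is.na(flip)) {
      out$status[i] <- "excluded_conflict"
      out$reason[i] <- sprintf(
        "outcome alleles %s/%s irreconcilable with exposure %s/%s",
        o_ea, o_oa, ea, oa)
      next
    }
    if (flip) { by <- -by; if (!is.na(fy)) fy <- 1 - fy }

    pal <- suppressMessages(is_palindromic(ea, oa))
    if (pal) {
      if (policy == "drop_all_palindromic") {
        out$status[i] <- "excluded_palindromic"
        out$reason[i] <- "palindromic and strand-ambiguous"
        next
      }
      fx <- out$eaf_exposure[i]
      inferable <- !is.na(fx) && !is.na(fy) &&
        min(fx, 1 - fx) < eaf_threshold && min(fy, 1 - fy) < eaf_threshold
      if (!inferable) {
        out$status[i] <- "excluded_palindromic"
        out$reason[i] <- "palindromic; allele frequency too close to 0.5 to infer strand"
        next
      }
      # frequencies on opposite sides of 0.5 mean the studies report opposite
      # strands: re-orient the outcome effect
      if ((fx < 0.5) != (fy < 0.5)) { by <- -by; fy <- 1 - fy }
    }

    out$beta_outcome[i] <- by
    out$se_outcome[i] <- sy
    out$eaf_outcome[i] <- fy
    out$status[i] <- if (!is.na(out$proxy_of[i])) "proxy_substituted" else "included"
  }

  structure(out, class = c("mr_harmonized", "data.frame"),
            policy = policy, eaf_threshold = eaf_threshold)
}

#' Analysis-ready subset of a harmonized instrument table
#'
#' @param h An `mr_harmonized` data frame.
#' @return Rows with status `included` or `proxy_substituted`.
#' @export
included <- function(h) {
  h[h$status %in% c("included", "proxy_substituted"), , drop = FALSE]
}

# strict inputs for estimators: included rows with finite effect columns
mr_inputs <- function(h) {
  if (!all(c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
           %in% names(h))) {
    mr_error("expected a harmonized instrument table", "mr_schema_error")
  }
  d <- included(h)
  stopifnot(all(is.finite(d$beta_exposure)), all(is.finite(d$beta_outcome)),
            all(d$se_exposure > 0), all(d$se_outcome > 0))
  d
}

#' Read GWAS summary statistics from a delimited text file
#'
#' The delimiter is inferred from the extension (`.csv` comma, otherwise tab).
#' `column_map` maps the canonical field names (`rsid`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `or`, `se`, `pvalue`) to the file's column
#' headers; exactly one of `beta`/`or` must be mapped, and an odds-ratio
#' column is converted to log-odds on read. Rows whose numeric fields fail to
#' parse (or carry non-positive standard errors) are skipped with a warning;
#' the skip count is recorded in attribute `n_skipped`.
#'
#' @param path File path.
#' @param column_map Named list or character vector, canonical -> file column.
#' @return Data frame of variant associations on the beta scale.
#' @export
read_summary_stats <- function(path, column_map) {
  if (!file.exists(path)) {
    mr_error(paste("no such file:", path), "mr_io_error")
  }
  column_map <- as.list(column_map)
  mandatory <- c("rsid", "effect_allele", "other_allele", "se", "pvalue")
  miss <- setdiff(mandatory, names(column_map))
  if (length(miss)) {
    mr_error(paste("column_map lacks mandatory mapping(s):",
                   paste(miss, collapse = ", ")), "mr_config_error")
  }
  has_beta <- "beta" %in% names(column_map)
  has_or <- "or" %in% names(column_map)
  if (has_beta == has_or) {
    mr_error("column_map must name exactly one of 'beta' or 'or'",
             "mr_config_error")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  for (col in unlist(column_map)) {
    if (!col %in% names(raw)) {
      mr_error(paste("mapped column absent from file:", col), "mr_config_error")
    }
  }
  num <- function(field) suppressWarnings(as.numeric(raw[[column_map[[field]]]]))
  eff <- if (has_beta) num("beta") else num("or")
  out <- data.frame(
    rsid = raw[[column_map$rsid]],
    effect_allele = toupper(raw[[column_map$effect_allele]]),
    other_allele = toupper(raw[[column_map$other_allele]]),
    eaf = if ("eaf" %in% names(column_map)) num("eaf") else NA_real_,
    beta = eff,
    se = num("se"),
    pvalue = num("pvalue"),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$beta) | !is.finite(out$se) | out$se <= 0 |
    !is.finite(out$pvalue) | out$pvalue < 0 | out$pvalue > 1 |
    (has_or & out$beta <= 0)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped in ", basename(path))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (has_or) out$beta <- or_to_beta(out$beta)
  structure(validate_associations(out),
            n_skipped = sum(bad),
            effect_converted_from_or = has_or)
}

#' Bundled bidirectional vitamin D / ADHD summary statistics
#'
#' Plain-text transcriptions of the published instrument tables for the
#' bidirectional analysis of serum 25-hydroxyvitamin D (25(OH)D) and attention
#' deficit/hyperactivity disorder (ADHD), exactly as printed, with LD proxies
#' already substituted (`proxy_of` records the lead). Odds ratios are
#' converted to log-odds on load.
#'
#' * `vitd_to_adhd`: six 25(OH)D instruments (exposure GWAS N = 79,366,
#'   R-squared = 0.0284) against ADHD (19,099 cases / 34,194 controls,
#'   European ancestry).
#' * `adhd_to_vitd`: twelve ADHD loci (European effect estimates,
#'   SNP-heritability 0.216) against 25(OH)D; two leads have no usable proxy
#'   and are absent from the outcome table.
#'
#' @param name Fixture name.
#' @return List with elements `exposure` (an `mr_instruments` set on the beta
#'   scale), `outcome` (association table, beta scale), `proxies` (LD proxy
#'   table) and `metadata`.
#' @examples
#' fx <- mr_fixture("vitd_to_adhd")
#' nrow(fx$exposure)
#' @export
mr_fixture <- function(name = c("vitd_to_adhd", "adhd_to_vitd")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("vitd_to_adhd", "adhd_to_vitd")) {
    mr_error(paste0("unknown fixture '", paste(name, collapse = ","),
                    "'; available: vitd_to_adhd, adhd_to_vitd"),
             "mr_lookup_error")
  }
  path <- function(f) system.file("extdata", f, package = "mrkit", mustWork = TRUE)
  proxies <- read.delim(path("ld_proxies.tsv"), stringsAsFactors = FALSE)

  if (name == "vitd_to_adhd") {
    ex <- read.delim(path("vitd_adhd_exposure.tsv"), stringsAsFactors = FALSE)
    ou <- read.delim(path("vitd_adhd_outcome.tsv"), stringsAsFactors = FALSE)
    ou$beta <- or_to_beta(ou$or); ou$or <- NULL
    meta <- list(
      exposure_name = "ln 25(OH)D", outcome_name = "ADHD",
      n_exposure = 79366L, variance_explained = 0.0284,
      n_outcome = 53293L, n_cases = 19099L, n_controls = 34194L,
      outcome_trait_type = "binary", exposure_trait_type = "continuous")
    ex <- validate_associations(ex)
    set <- structure(ex, class = c("mr_instruments", "data.frame"),
                     p_threshold = 5e-8,
                     exposure_name = meta$exposure_name,
                     variance_explained = meta$variance_explained,
                     sample_size = meta$n_exposure)
  } else {
    ex <- read.delim(path("adhd_vitd_exposure.tsv"), stringsAsFactors = FALSE)
    ex$beta <- or_to_beta(ex$or); ex$or <- NULL
    ou <- read.delim(path("adhd_vitd_outcome.tsv"), stringsAsFactors = FALSE)
    meta <- list(
      exposure_name = "ADHD", outcome_name = "ln 25(OH)D",
      n_exposure = 53293L, n_cases = 19099L, n_controls = 34194L,
      variance_explained = 0.216,
      n_outcome = 79366L,
      outcome_trait_type = "continuous", exposure_trait_type = "binary")
    ex <- validate_associations(ex)
    # selection to genome-wide significance was performed in the source GWAS
    # on its full sample; the bundled effect estimates are European-ancestry
    set <- structure(ex, class = c("mr_instruments", "data.frame"),
                     p_threshold = 5e-8,
                     exposure_name = meta$exposure_name,
                     variance_explained = meta$variance_explained,
                     sample_size = meta$n_exposure)
  }
  list(exposure = set, outcome = validate_associations(ou),
       proxies = proxies, metadata = meta)
}
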