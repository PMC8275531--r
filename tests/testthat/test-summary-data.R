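# Data model: odds-ratio conversion, palindrome classification, instrument
# selection, proxy choice, harmonization and the bundled fixtures.

test_that("odds ratios convert to log-odds with the natural logarithm", {
  expect_identical(or_to_beta(1.0), 0)
  expect_equal(or_to_beta(1.0313), 0.030819, tolerance = 1e-4)
  expect_equal(or_to_beta(0.92635), -0.076504, tolerance = 1e-4)
  expect_equal(or_to_beta(1.11305), 0.10710, tolerance = 1e-4)
  expect_error(or_to_beta(0), class = "mr_domain_error")
  expect_error(or_to_beta(-1.2), class = "mr_domain_error")
})

test_that("palindrome classification follows complement pairs and is symmetric", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("T", "C"))
  alleles <- c("A", "C", "G", "T")
  for (a in alleles) for (b in setdiff(alleles, a)) {
    expect_identical(is_palindromic(a, b), is_palindromic(b, a))
  }
  expect_message(res <- is_palindromic("GTC", "G"), "indel")
  expect_false(res)
})

test_that("instrument selection filters on the p-value threshold", {
  fx <- mr_fixture("vitd_to_adhd")
  sel <- select_instruments(as.data.frame(fx$exposure), p_threshold = 5e-8)
  expect_equal(nrow(sel), 6L)
  expect_equal(attr(sel, "p_threshold"), 5e-8)

  all_in <- select_instruments(as.data.frame(fx$exposure), p_threshold = 1.0)
  expect_equal(nrow(all_in), 6L)

  # the strongest association's p-value underflows double precision to 0 and
  # survives any representable threshold
  tight <- select_instruments(as.data.frame(fx$exposure), p_threshold = 1e-200)
  expect_equal(tight$rsid, "rs3755967")

  fr <- mr_fixture("adhd_to_vitd")
  expect_warning(
    select_instruments(as.data.frame(fr$exposure), p_threshold = 1e-15),
    "no variants")
  empty <- suppressWarnings(
    select_instruments(as.data.frame(fr$exposure), p_threshold = 1e-15))
  expect_equal(nrow(empty), 0L)

  dup <- rbind(as.data.frame(fx$exposure), as.data.frame(fx$exposure)[1, ])
  expect_error(select_instruments(dup, 5e-8), class = "mr_domain_error")
})

test_that("proxy choice ranks by r2 then distance, deterministically", {
  fx <- mr_fixture("vitd_to_adhd")
  best <- select_proxy("rs17216707", fx$proxies)
  expect_equal(best$proxy_rsid, "rs209955")
  expect_equal(best$r2, 0.4115)
  expect_equal(best$distance, -9491)

  cands <- data.frame(
    lead_rsid = "rsL",
    proxy_rsid = c("rsP1", "rsP2", "rsP3", "rsP4"),
    r2 = c(0.9, 0.5, 0.9, 0.9),
    distance = c(10, 5000, -100, 100),
    a1 = c("A", "A", "A", "A"), a2 = c("T", "G", "G", "C"),
    stringsAsFactors = FALSE)
  # first criterion (r2) dominates; distance then picks the palindromic rsP1
  expect_equal(select_proxy("rsL", cands)$proxy_rsid, "rsP1")
  # permuting candidate order never changes the selection
  set.seed(42)
  for (s in 1:5) {
    perm <- cands[sample.int(nrow(cands)), ]
    expect_equal(select_proxy("rsL", perm)$proxy_rsid, "rsP1")
  }
  # the reverse-direction criteria ordering avoids palindromic proxies
  got <- select_proxy("rsL", cands,
                      criteria = c("max_r2", "non_palindromic",
                                   "min_abs_distance"))
  expect_equal(got$proxy_rsid, "rsP3")
  # r2 threshold filter can empty the candidate list
  low <- cands; low$r2 <- 0.30
  expect_null(select_proxy("rsL", low, r2_min = 0.40))
  # absence (no candidates for this lead) is a value, not an error
  expect_null(select_proxy("rs_absent", cands))
})

test_that("proxy substitution swaps in the proxy's own association record", {
  inst <- select_instruments(data.frame(
    rsid = c("rsA", "rsLead"), effect_allele = c("A", "T"),
    other_allele = c("G", "C"), eaf = c(0.3, 0.4),
    beta = c(0.05, 0.04), se = c(0.004, 0.004), pvalue = c(1e-12, 1e-10),
    stringsAsFactors = FALSE))
  ptab <- data.frame(lead_rsid = "rsLead", proxy_rsid = "rsProxy", r2 = 0.8,
                     distance = -500, a1 = "A", a2 = "C",
                     stringsAsFactors = FALSE)
  prox <- data.frame(rsid = "rsProxy", effect_allele = "A", other_allele = "C",
                     eaf = 0.42, beta = 0.037, se = 0.005, pvalue = 2e-9,
                     stringsAsFactors = FALSE)
  out <- substitute_proxies(inst, available_rsids = c("rsA", "rsProxy"),
                            proxy_table = ptab, proxy_associations = prox)
  expect_equal(out$rsid, c("rsA", "rsProxy"))
  expect_equal(out$beta[2], 0.037)   # used as reported, not rescaled by r2
  expect_equal(out$proxy_of[2], "rsLead")
  # a lead present in the other study is left untouched
  expect_true(is.na(out$proxy_of[1]))
})

test_that("harmonization reproduces the fixture inclusion pattern", {
  h <- forward_harmonized()
  expect_s3_class(h, "mr_harmonized")
  expect_equal(nrow(h), 6L)
  expect_equal(nrow(included(h)), 5L)
  expect_equal(h$status[h$rsid == "rs8018720"], "excluded_palindromic")
  expect_equal(h$status[h$rsid == "rs209955"], "proxy_substituted")
  expect_equal(h$proxy_of[h$rsid == "rs209955"], "rs17216707")
  # input order preserved
  expect_equal(h$rsid[1:3], c("rs10741657", "rs10745742", "rs12785878"))

  hr <- reverse_harmonized()
  expect_equal(nrow(hr), 12L)
  expect_equal(nrow(included(hr)), 6L)
  expect_equal(sum(hr$status == "excluded_palindromic"), 4L)
  expect_equal(sum(hr$status == "excluded_missing"), 2L)
  expect_setequal(hr$rsid[hr$status == "excluded_missing"],
                  c("rs11420276", "rs5886709"))
})

test_that("allele swaps and strand flips re-orient the outcome effect", {
  exposure <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.05, se = 0.005, pvalue = 1e-10,
                         stringsAsFactors = FALSE)
  aligned <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                        eaf = 0.31, beta = 0.02, se = 0.01, pvalue = 0.05,
                        stringsAsFactors = FALSE)
  h0 <- harmonize(exposure, aligned)
  expect_equal(h0$beta_outcome, 0.02)

  swapped <- aligned
  swapped[, c("effect_allele", "other_allele")] <- c("G", "A")
  swapped$beta <- -swapped$beta
  swapped$eaf <- 1 - swapped$eaf
  h1 <- harmonize(exposure, swapped)
  # allele-flip invariance (frequency complement up to float round-trip)
  expect_equal(h0, h1, tolerance = 1e-15)

  flipped <- aligned   # opposite strand: A/G reported as T/C
  flipped$effect_allele <- "T"; flipped$other_allele <- "C"
  h2 <- harmonize(exposure, flipped)
  expect_equal(h2$beta_outcome, 0.02)
  expect_equal(h2$status, "included")

  conflict <- aligned
  conflict$effect_allele <- "A"; conflict$other_allele <- "C"
  h3 <- harmonize(exposure, conflict)
  expect_equal(h3$status, "excluded_conflict")
  expect_match(h3$reason, "irreconcilable")
  expect_true(is.na(h3$beta_outcome))
})

test_that("harmonization is idempotent and an identity on self", {
  fx <- mr_fixture("vitd_to_adhd")
  self <- harmonize(fx$exposure, as.data.frame(fx$exposure))
  inc <- included(self)
  expect_equal(inc$beta_outcome, inc$beta_exposure)

  h <- forward_harmonized()
  inc1 <- included(h)
  again <- harmonize(
    data.frame(rsid = inc1$rsid, effect_allele = inc1$effect_allele,
               other_allele = inc1$other_allele, eaf = inc1$eaf_exposure,
               beta = inc1$beta_exposure, se = inc1$se_exposure,
               pvalue = rep(1e-10, nrow(inc1)), proxy_of = inc1$proxy_of,
               stringsAsFactors = FALSE),
    data.frame(rsid = inc1$rsid, effect_allele = inc1$effect_allele,
               other_allele = inc1$other_allele, eaf = inc1$eaf_outcome,
               beta = inc1$beta_outcome, se = inc1$se_outcome,
               pvalue = rep(0.5, nrow(inc1)), stringsAsFactors = FALSE))
  expect_equal(included(again)$beta_outcome, inc1$beta_outcome)
  expect_equal(included(again)$se_outcome, inc1$se_outcome)
  expect_equal(nrow(included(again)), nrow(inc1))
})

test_that("palindromic variants can be kept when strand is frequency-inferable", {
  exposure <- data.frame(rsid = c("rs1", "rs2"),
                         effect_allele = c("A", "C"), other_allele = c("T", "G"),
                         eaf = c(0.10, 0.49), beta = c(0.05, 0.04),
                         se = c(0.005, 0.005), pvalue = c(1e-10, 1e-10),
                         stringsAsFactors = FALSE)
  # rs1 reported on the opposite strand side: outcome eaf near 1 - 0.10
  outcome <- data.frame(rsid = c("rs1", "rs2"),
                        effect_allele = c("A", "C"), other_allele = c("T", "G"),
                        eaf = c(0.88, 0.50), beta = c(0.02, 0.01),
                        se = c(0.01, 0.01), pvalue = c(0.5, 0.5),
                        stringsAsFactors = FALSE)
  dropped <- harmonize(exposure, outcome, policy = "drop_all_palindromic")
  expect_equal(dropped$status, rep("excluded_palindromic", 2))

  kept <- harmonize(exposure, outcome, policy = "keep_inferable_palindromic")
  # rs1 inferable (maf 0.10/0.12): frequencies disagree in side, so flip
  expect_equal(kept$status[1], "included")
  expect_equal(kept$beta_outcome[1], -0.02)
  expect_equal(kept$eaf_outcome[1], 0.12)
  # rs2 ambiguous (maf ~0.5 in both): still excluded
  expect_equal(kept$status[2], "excluded_palindromic")
})

test_that("summary-statistics reader maps columns, converts OR, skips bad rows", {
  path <- system.file("extdata", "vitd_adhd_exposure.tsv", package = "mrkit")
  cm <- list(rsid = "rsid", effect_allele = "effect_allele",
             other_allele = "other_allele", eaf = "eaf", beta = "beta",
             se = "se", pvalue = "pvalue")
  x <- read_summary_stats(path, cm)
  expect_equal(nrow(x), 6L)
  expect_equal(x$beta[x$rsid == "rs8018720"], -0.017)

  opath <- system.file("extdata", "vitd_adhd_outcome.tsv", package = "mrkit")
  ocm <- list(rsid = "rsid", effect_allele = "effect_allele",
              other_allele = "other_allele", or = "or", se = "se",
              pvalue = "pvalue")
  y <- read_summary_stats(opath, ocm)
  expect_equal(y$beta[y$rsid == "rs12785878"], log(1.0313))
  expect_true(attr(y, "effect_converted_from_or"))

  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("snp\tA1\tA2\tb\ts\tp",
               "rs1\tA\tG\t0.05\t0.004\t1e-12",
               "rs2\tT\tC\tnot_a_number\t0.004\t1e-9"), tmp)
  cm2 <- list(rsid = "snp", effect_allele = "A1", other_allele = "A2",
              beta = "b", se = "s", pvalue = "p")
  expect_warning(z <- read_summary_stats(tmp, cm2), "1 malformed")
  expect_equal(nrow(z), 1L)
  expect_equal(attr(z, "n_skipped"), 1L)

  expect_error(read_summary_stats(tmp, cm2[-1]), class = "mr_config_error")
  expect_error(read_summary_stats(tmp, c(cm2, list(or = "b"))),
               class = "mr_config_error")
})

test_that("bundled fixtures carry the published values and metadata", {
  fx <- mr_fixture("vitd_to_adhd")
  expect_equal(nrow(fx$exposure), 6L)
  expect_equal(fx$exposure$beta[fx$exposure$rsid == "rs3755967"], -0.089)
  expect_equal(fx$metadata$n_exposure, 79366L)
  expect_equal(fx$metadata$variance_explained, 0.0284)
  expect_equal(fx$metadata$n_cases, 19099L)

  fr <- mr_fixture("adhd_to_vitd")
  expect_equal(nrow(fr$exposure), 12L)
  expect_equal(fr$exposure$beta[fr$exposure$rsid == "rs1427829"],
               log(1.08567))
  expect_equal(fr$metadata$variance_explained, 0.216)
  expect_equal(nrow(fr$outcome), 10L)

  expect_error(mr_fixture("nope"), class = "mr_lookup_error")
})
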