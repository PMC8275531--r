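---
title: "Methods: two-sample Mendelian randomization in mrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Two-sample Mendelian randomization (MR) treats genetic variants as
instrumental variables for an exposure. For instrument $j$, let
$\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association with the exposure in
one GWAS and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its association with the
outcome in an independent GWAS. Under the instrumental-variable assumptions —
association with the exposure, no association with confounders, and no effect
on the outcome except through the exposure — each ratio
$\theta_j = \beta_{Yj}/\beta_{Xj}$ estimates the same causal effect $\theta$.
For binary outcomes all arithmetic is on the log-odds scale; reported odds
ratios are converted with the natural logarithm (`or_to_beta()`).

The package works on plain summary statistics: a delimited table per study
(one row per variant), read through a user-supplied column map
(`read_summary_stats()`), so any GWAS export can be used without
reformatting.

## Instrument selection, proxies, harmonization

`select_instruments()` keeps variants with $p$ below a genome-wide threshold
(default $5\times10^{-8}$). When a selected variant is absent from the other
study, `select_proxy()` ranks user-supplied LD candidates — filtered to
$r^2 \ge 0.40$ — lexicographically, by default highest $r^2$ then smallest
absolute distance to the lead; an alternative ordering additionally prefers
non-palindromic alleles. Ties break by rsid so the choice is deterministic
under any candidate ordering. The proxy's own association estimates are used
as reported (not rescaled by $r^2$), which is the convention when the proxy
is measured directly in both studies. LD lookups come from a local TSV: the
package performs no online queries.

`harmonize()` puts both studies on a common effect allele. If the outcome
study reports the swapped allele pair, the outcome effect is negated and the
frequency complemented; if it reports the opposite strand, alleles are
complemented and re-matched; records that neither operation reconciles are
excluded with an explicit reason, never silently dropped. Palindromic
variants (A/T or C/G) are excluded by default (`drop_all_palindromic`),
because strand cannot be verified from the alleles; an opt-in policy
(`keep_inferable_palindromic`) retains palindromic variants whose
minor-allele frequency is below 0.42 in both studies and infers orientation
by frequency matching. The default reproduces the conservative practice of
dropping every palindromic variant regardless of frequency; the bound 0.42
is the conventional ambiguity cut-off and is configurable. Matching is by
rsid; positions are annotation only, which sidesteps genome-build
differences between studies.

Harmonized rows carry a status: `included`, `proxy_substituted` (included in
analysis, with the lead recorded in `proxy_of`), `excluded_palindromic`,
`excluded_missing`, or `excluded_conflict`. Estimators operate on the first
two.

## Estimators

All estimators use inverse-variance weights based on the outcome standard
errors, $w_j = \sigma_{Yj}^{-2}$, and ignore exposure-side uncertainty in
the point estimate (the usual NOME approximation for strong instruments).

* **Wald ratio** (`mr_wald_ratio()`): $\theta_j$ with first-order SE
  $\sigma_{Yj}/|\beta_{Xj}|$ and a two-sided normal $p$. The first-order SE
  reproduces published single-SNP tables; a second-order option adds
  $\beta_{Yj}^2\sigma_{Xj}^2/\beta_{Xj}^4$ under the root.
* **IVW** (`mr_ivw()`): weighted regression of $\beta_{Yj}$ on $\beta_{Xj}$
  through the origin, $\hat\theta = \sum w_j\beta_{Xj}\beta_{Yj} / \sum
  w_j\beta_{Xj}^2$. The default multiplicative random-effects model inflates
  the fixed-effect SE by $\max\{1, \sqrt{Q/(J-1)}\}$ with
  $Q = \sum w_j(\beta_{Yj}-\hat\theta\beta_{Xj})^2$; flooring at 1 means
  underdispersion never shrinks the SE below the fixed-effect value.
  $p$-values are two-sided normal.
* **MR-Egger** (`mr_egger()`): after orienting every instrument to
  $\beta_{Xj} > 0$, a weighted regression *with* intercept. The intercept
  estimates average directional pleiotropy (valid under InSIDE: instrument
  strength independent of direct effects); the slope is the
  pleiotropy-adjusted effect. Both SEs use the residual scale
  $\sqrt{Q_{egger}/(J-2)}$ floored at 1, and $p$-values are two-sided $t$
  with $J-2$ df. This floor-and-$t$ convention reproduces published Egger
  rows to the printed digits on the bundled reverse-direction fixture.
* **Weighted median** (`mr_weighted_median()`): order the ratio estimates,
  form standardized mid-cumulative weights
  $s_j = (\sum_{k\le j} w^{(r)}_k - w^{(r)}_j/2)/\sum_k w^{(r)}_k$ with ratio
  weights $w^{(r)}_j = (\beta_{Xj}/\sigma_{Yj})^2$, and linearly interpolate
  to $s = 0.5$. Consistent while valid instruments carry at least half the
  weight. SE by seeded parametric bootstrap (each $\hat\beta$ perturbed by
  its Gaussian SE), default 1000 replicates, seed 1.
* **Mode-based estimate** (`mr_mode()`): the argmax over a 512-point grid of
  a Gaussian-kernel density of the ratio estimates, weighted
  (precision weights, "weighted mode") or uniform ("simple mode").
  Bandwidth follows the modified Silverman rule
  $h = \varphi\,0.9\,\min\{\mathrm{sd},\mathrm{mad}\}\,J^{-1/5}$ with
  $\varphi = 1$ by default; the grid spans the ratio range ± 3 bandwidths.
  If all ratios coincide the bandwidth is zero and the common ratio is
  returned. Mode-based point estimates are sensitive to the bandwidth
  pairing, so they should be read as sensitivity analyses rather than exact
  reproducible quantities.

`mr_all_estimates()` collects all five in a table; methods whose instrument
minimum (IVW 2, Egger/median/mode 3) is not met are reported as not run.

## MR-PRESSO

`mr_presso()` tests for horizontal pleiotropy via a residual sum of squares:
each instrument's squared deviation from the leave-one-out IVW fit, weighted
by $\sigma_{Yj}^{-2}$. The null distribution is simulated (default 1000
replicates, explicit seed): outcome effects are redrawn from
$N(\hat\theta_{(-j)}\beta_{Xj}, \sigma_{Yj})$ and the statistic recomputed,
leave-one-out estimates included. The global $p$ uses the add-one Monte
Carlo estimator $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$, so it is never
exactly zero. Per-SNP outlier $p$-values come from each SNP's simulated
residual distribution, Bonferroni-adjusted; flagged SNPs are removed for the
corrected estimate, and a resampling distortion test compares raw and
corrected estimates. The raw and corrected estimates are the IVW point with
the multiplicative random-effects SE and a two-sided $t$ reference at $J-1$
df — the convention that reproduces the published "raw" rows. At least four
instruments are required.

## Diagnostics

* `cochran_q()`: $Q$ about the no-intercept (df $J-1$) or Egger intercept
  (df $J-2$) fit, upper-tail chi-square.
* `f_statistic()`: the standard multi-instrument strength statistic
  $F = \frac{R^2}{1-R^2}\cdot\frac{n-k-1}{k}$; $F < 10$ flags a weak
  instrument. For the bundled forward fixture this gives 386.6 from
  $R^2 = 0.0284$, $n = 79{,}366$, $k = 6$. The source publication prints
  1558.762 (and 21,867.14 for the reverse direction); neither value is
  consistent with any standard formula at the stated inputs, so we treat
  those as errata and report the standard formula — the qualitative
  conclusion (strong instruments, $F \gg 10$) is unchanged.
* `leave_one_out()`: the default IVW on each $J-1$ subset. Because it is
  unknowable whether a published leave-one-out interval applied the
  random-effects floor, both the floored and the fixed-effect SE are
  reported per row.
* `single_snp_table()`, `funnel_data()`, `scatter_data()`: plot-ready tables
  (forest rows in input order with method summaries last; funnel precision
  $|\beta_{Xj}|/\sigma_{Yj}$; scatter points plus per-method fitted lines).
  Rendering is left to the caller; the data tables carry the content.

## Power

For a binary outcome, `mr_power_binary()` uses the non-centrality-parameter
approximation $NCP = N R^2 K(1-K) b^2$ with $b = |\log OR|$, $K$ the case
fraction and $R^2$ the exposure variance explained, giving
$\mathrm{power} = \Phi(\sqrt{NCP} - z_{1-\alpha/2})$ at two-sided level
$\alpha$ (default 0.05). `mr_detectable_or()` inverts this in closed form,
$b = (z_{1-\alpha/2} + z_{power})/\sqrt{N R^2 K(1-K)}$; the round-trip is
exact to $10^{-10}$. Power is symmetric in $OR \leftrightarrow 1/OR$. With
the bundled forward-study parameters ($N = 53{,}293$, $K = 19{,}099/53{,}293$,
$R^2 = 0.0284$) the detectable OR at 80% power is 1.162 and power at
OR 1.27 exceeds 0.99.

## The synthetic-data generator

`mr_scenario()`/`simulate_two_sample()` generate paired summary statistics
directly from the linear structural model the estimators assume:
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma)$ exposure effects, direct
(pleiotropic) effects $\alpha_j$ with configurable mean, sd and correlation
$\rho$ with $\gamma_j$ (nonzero $\rho$ violates InSIDE), and observed
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj})$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj})$.

Defaults emulate the bundled study: $J = 6$, $\gamma \sim N(0.04, 0.03)$
(the magnitude of the printed exposure betas), exposure GWAS $N = 79{,}366$,
binary outcome study $N = 53{,}293$ with case fraction $19{,}099/53{,}293$,
$\theta = 0$, no pleiotropy. Outcome SEs use the standard
allele-frequency-aware GWAS approximation
$\sigma_{Yj} = 1/\sqrt{2p_j(1-p_j)\,N\,K(1-K)}$ (binary; drop $K(1-K)$ for
continuous) with $p_j \sim U(0.05, 0.95)$ — at the default sample sizes this
spans 0.013–0.030, bracketing the per-variant SEs of real ADHD-scale GWAS.
Exposure SEs are calibrated as
$\sigma_{Xj} = |\gamma_j|\sqrt{n_{ref}/n_{exposure}}/(1.5\,z_{gw})$ with
$z_{gw}$ the two-sided $5\times10^{-8}$ quantile, so essentially all draws
clear genome-wide significance — instruments are strong by construction.
Palindromic alleles and outcome-missing variants are injected on request,
with the ground truth returned alongside.

What the generator does **not** emulate: LD between instruments (the target
design uses independent loci), winner's-curse inflation of selected exposure
effects, allele-frequency-dependent exposure SEs, sample overlap, or
population stratification. Passing recovery tests therefore demonstrate
correctness of the estimators under their own assumptions — not robustness
to those real-data pathologies.

`recovery_experiment()` runs simulate → harmonize → estimate over replicate
seeds derived deterministically from the scenario seed and summarises bias,
empirical vs estimated SE, 95% CI coverage, and the rejection rates of the
Egger-intercept and Q tests. The package's validation experiments use 500
replicates at $J = 100$ (IVW coverage; Egger-intercept recovery of a mean
pleiotropic effect of 0.02), sizes at which Monte-Carlo error is small
relative to the tested bands while the experiment stays quick. For the
pleiotropy-recovery scenario the exposure-effect sd is set to 0.01 so that
effectively all $\gamma_j > 0$: with mixed signs, Egger's orientation step
flips part of the $\alpha_j$ and the intercept estimates the *oriented* mean
direct effect rather than $\mu_\alpha$ — a real property of the estimator,
not an artifact.

## Numerical and design choices

* Odds ratios convert with the natural log; published effect-ratio tables
  are reproduced under that base.
* P-values may underflow double precision in very strong exposure hits; the
  data model accepts $p = 0$ and selection uses a strict `<`.
* SE floors: IVW multiplier $\max(1,\cdot)$ and Egger residual scale
  $\max(1,\cdot)$ — both prevent underdispersed data from producing
  anti-conservative intervals, and both match published conventions.
* Ratio $p$-values are reported unadjusted; a single-SNP finding that would
  not survive multiplicity correction should be read accordingly.
* Bootstrap and simulation are bit-reproducible for a fixed seed; default
  `n_boot` and `n_sim` are 1000.
* Reports: TSVs print three decimals (the precision of published MR
  tables); `report.json` keeps full precision and contains no timestamps,
  so identical configs and seeds give byte-identical reports.

## Limitations

Beyond the generator's simplifications above: no multivariable MR, no
Steiger directionality filtering, no $I^2$/model-selection framework, no LD
computation from genotype panels, and no online proxy lookups. Exact
reproduction of published single-SNP standard errors is limited by the
printed precision of source tables when the underlying unrounded estimates
are unavailable.
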