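---
title: "Simulating and testing asymmetric extremes of the BMI distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and testing asymmetric extremes of the BMI distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmitails)
```

## The scientific problem

Case-control genetic studies of body-weight regulation sometimes contrast
clinically ascertained *extremes* of the BMI distribution: severely obese
individuals against persistently thin ones, each also compared against
non-extreme population controls. Such designs gain power, but they are
asymmetric by construction: severe childhood-onset obesity corresponds to
roughly the top 0.15% of the population BMI distribution, while healthy
persistent thinness (BMI at or below 19) is far less extreme, roughly the
bottom 2.8%. A variant with a perfectly additive effect across the whole
BMI range will therefore show a *larger* odds ratio in the obese contrast
than in the thin contrast — not because its biology differs between the
two ends, but because the obese cases deviate further from the population
mean. Any claim that a locus behaves "differently in thinness than in
obesity" must first rule out this ascertainment artifact.

`bmitails` implements the simulation-based machinery for doing so:

1. an **additive polygenic simulator** reproducing the ascertainment
   scheme exactly,
2. a **per-locus empirical deviation-from-additivity test**,
3. **genetic risk score (GRS) ordinal analysis** with a simulation null
   for the equal-odds question,
4. **direction-of-effect enrichment** and a **fixed-effect replication
   meta-analysis** with explicit decision rules, and
5. scalar association helpers (allelic ORs, CI/SE conversion, Nagelkerke
   R², liability-scale heritability conversion).

## The additive simulator

A locus panel specifies, per biallelic locus $j$, the effect-allele
frequency $p_j$ and the per-allele effect $\beta_j$ in phenotype-SD units
(the effect allele is the BMI-increasing allele). Genotypes are two
independent allele draws, so dosages are $g_{ij} \sim \mathrm{Bin}(2,
p_j)$ with Hardy–Weinberg class frequencies, and loci are independent
(linkage equilibrium — appropriate for a pruned panel of independent
association signals, not for dense local variation). The phenotype is

$$y_i = \sum_j \beta_j\,(g_{ij} - 2p_j) + \varepsilon_i,
  \qquad \varepsilon_i \sim N\!\Big(0,\; 1 - \sum_j 2p_j(1-p_j)\beta_j^2\Big),$$

i.e. centered dosages plus a Gaussian residual scaled so the total
variance is 1. Centering makes SD-unit thresholds meaningful, and the
standardization matches how published BMI effect sizes are estimated.
A panel whose genetic variance reaches 1 leaves no residual variance and
is rejected.

Two features of the realized BMI distribution are then imposed:

* **lower-tail truncation** at −3 SD (default): phenotypes that extreme
  are removed before any sampling, since the corresponding BMI values are
  not compatible with healthy human life. Truncation precedes percentile
  computation, so all sampling fractions refer to the truncated
  distribution.
* **asymmetric extreme sampling** by empirical order statistics: the
  obese pool is the top 0.15% of the truncated distribution, the thin
  pool the bottom 2.8%, and the control pool the (2.8%, 75%] percentile
  band. Requested cohort sizes (defaults 1,456 obese / 1,471 thin /
  6,460 controls per replicate of one million individuals) are drawn
  uniformly without replacement from those pools. Ties are broken by
  stable index order.

The control band's upper bound emulates the upper limit of a BMI 19–30
control range. The exact population percentile of BMI 30 is not sharply
defined; 0.75 (roughly the overweight/obesity boundary in the UK adult
population) is the default and is configurable. Whether controls should
be drawn on the truncated or untruncated percentile scale is likewise a
design choice; the package draws them on the truncated scale, consistent
with truncation being applied before any sampling.

`scale_design()` shrinks the population and the three cohort sizes by the
same factor (flooring, so pools always cover requests). Because tail
fractions are preserved, the ascertainment geometry — and hence the
asymmetry phenomenon — survives down-scaling; only Monte-Carlo noise
grows. Test-suite and example runs use $n = 10^5$ per replicate with 200
replicates; full-scale runs ($10^6 \times 10{,}000$) are supported by the
same code path.

All randomness flows from a single master seed: ensemble drivers draw one
child seed per replicate, so any replicate can be reproduced in
isolation.

## The deviation-from-additivity test

`run_ensemble()` simulates the whole design $R$ times and records, per
locus and replicate, the allelic odds ratios of both contrasts (obese vs
controls and controls vs thin, lower-BMI group as reference). For an
observed odds ratio $\mathrm{OR}^{obs}_j$ — an *input*, taken from
association summary statistics, never recomputed here — the test
statistic is the absolute deviation on the OR scale from the simulated
mean, and the empirical p-value is the fraction of replicates whose own
deviation is equal to or larger:

$$p_j = \frac{1}{R} \#\Big\{r : \big|\mathrm{OR}^{sim}_{jr} -
  \overline{\mathrm{OR}^{sim}_j}\big| \ge
  \big|\mathrm{OR}^{obs}_j - \overline{\mathrm{OR}^{sim}_j}\big|\Big\}.$$

Numerical choices worth stating:

* "equal or larger" is honored with a $10^{-12}$ relative tolerance,
  because exact ties are otherwise destroyed by floating-point
  representation of the two subtractions;
* a zero exceedance count is stored as 0 and rendered `"< 1/R"`; an
  optional $(k+1)/(R+1)$ mode exists for calibration work but is off by
  default, matching the plain-count definition;
* deviation is measured on the OR scale, not the log-OR scale, matching
  the statistic's definition above;
* when a desk-scale replicate produces a zero allele count in a small
  cohort, that table receives the Haldane–Anscombe +0.5 correction.
  Observed and simulated draws pass through identical code, so the
  rank-based p-value remains exchangeable.

Correction for multiple testing uses the Bonferroni threshold
$\alpha / (\text{loci} \times \text{analyses})$; for 97 loci and two
contrasts, $0.05/194 \approx 2.6\times10^{-4}$.

The test's calibration is itself a tested property: with the "observed"
OR drawn from the additive model (each replicate serving once as the
observed value against the others), the p-values must be uniform on
their grid — the suite checks a Kolmogorov–Smirnov test and a nominal
rate of 5% over 8,000 locus-replicates.

## GRS ordinal analysis

`compute_grs()` forms the weighted dosage sum $\sum_j w_j d_{ij}$ and
standardizes it by the sample mean and SD (denominator $n-1$) over the
pooled analysis set — standardization happens once, before regression.

`fit_ordinal()` maximizes the cumulative-logit likelihood
$\mathrm{logit}\,P(Y \le k) = \alpha_k - \eta_{ik}$ over ordered BMI
categories (thin < control < obese). Three modes: `proportional` (one
shared coefficient per predictor), `partial` (the score, and designated
covariates, get cutpoint-specific coefficients), and `full` (everything
varies). Cutpoint ordering is enforced by reparameterization (first
cutpoint plus positive log-increments). The optimizer is BFGS from the
closed-form intercept-only start; non-proportional fits warm-start from
the proportional solution, which guarantees the nested log-likelihood
ordering that the equal-odds likelihood-ratio test
(`equal_odds_lrt()`) relies on. The proportional fit is verified against
an independent implementation (`MASS::polr`) and a brute-force
grid-search maximizer in the test suite.

Because the sampling design itself induces unequal per-cutpoint odds
(the asymmetry above), the observed equal-odds statistic is compared
against its *simulation null*: `grs_null_distribution()` refits the
ordinal model on each simulated cohort, and `grs_simulation_pvalue()`
counts strictly larger simulated statistics. Per-category mean scores
are compared with `mean_grs_category_test()`, formalized as a one-sample
t statistic against the spread of per-replicate simulated means (with
$R-1$ degrees of freedom); the choice of the one-sample form is a
package decision where several t-test variants would be defensible.
Which statistic feeds the simulation comparison is likewise a choice:
the equal-odds LRT statistic is used, as the natural scalar summary of
"are the odds the same across categories".

## Enrichment, meta-analysis, replication

* `binomial_consistency_test(k, n)`: exact upper-tail
  $P(X \ge k),\, X \sim \mathrm{Bin}(n, 1/2)$ — at $k = n$ this is
  $0.5^n$, the closed form used as its own oracle.
* `count_consistent_nominal()` harmonizes alleles before counting:
  swapped effect/other alleles invert the sign; strand flips are
  complemented; irresolvable pairs are excluded with a warning. Proxy
  variant substitution is out of scope — inputs must be pre-matched by
  variant.
* `fixed_effect_meta()` is the inverse-variance combination
  ($w_s = 1/SE_s^2$), with `cochran_q()` for heterogeneity. SEs are
  back-calculated from published 95% CIs via
  $(\ln CI_{hi} - \ln CI_{lo})/(2 \times 1.96)$; 1.96 (not a
  higher-precision quantile) is used throughout so conversions round-trip
  with conventionally reported intervals. Heterogeneity includes the
  discovery study when it is supplied as one of the rows. No correction
  for shared controls across replication cohorts is applied; rows whose
  replication evidence comes from a single independent cohort are
  unaffected by that limitation.
* `replication_decision()` applies the three-criterion rule: consistent
  direction in every replication cohort, $p < 0.05$ in at least one, and
  a genome-wide significant meta-analysis p (default $5\times10^{-8}$,
  strict option $1.17\times10^{-8}$ for denser variant sets).

## Worked example

A small desk-scale run (the object prints its own summary):

```{r example, eval = FALSE}
panel <- locus_panel("strong_locus", "A", "T", eaf = 0.4, beta = 0.08)
design <- cohort_design(n_replicates = 100)
ens <- run_ensemble(panel, design, seed = 99)
apply(ens$ors, 3, mean)
#> case_vs_control control_vs_thin
#>        1.336535        1.156299
```

Both contrasts exceed 1, and the obese contrast is visibly larger — the
pure-ascertainment asymmetry. A numerical-integration oracle for the
truncated liability model (three Gaussian mixture components, one per
genotype) predicts 1.332 and 1.157 for this configuration; the simulated
means agree within Monte-Carlo error. This is the mechanism by which a
locus can show, say, OR 1.4 against obesity but only OR 1.15 against
thinness while acting perfectly additively.

## What the simulator does and does not emulate

The generator reproduces the *design*: panel-driven additive genetics,
Hardy–Weinberg genotypes, a standardized Gaussian-residual phenotype,
lower-tail truncation, and rank-based asymmetric tail sampling. It does
not emulate linkage disequilibrium between loci, imputation dosage
uncertainty, X-chromosome dosage, covariate structure (age, sex,
principal components), gene–environment interaction, or genuinely
non-additive (dominance/epistatic) effects. Passing calibration tests
therefore show that the *test machinery* is correct under the additive
null — they cannot show that real cohorts are free of confounding, and
observed-data ORs carry covariate adjustments the simulator does not
model (simulated ORs are unadjusted allelic ORs, the appropriate
counterpart in a confounder-free simulation).

## Numerical and scale choices

* Test-suite problem sizes: calibration uses a 20-locus panel, 200
  replicates of $10^5$ individuals; the asymmetry check uses 100
  replicates of $10^6$; ordinal type-I calibration uses 500 datasets of
  $n = 2{,}000$. These sizes keep Monte-Carlo error well inside the
  asserted tolerances.
* The liability-scale heritability conversion follows the standard
  threshold-model formula
  $h^2_{liab} = h^2_{obs}\, K^2(1-K)^2 / (z^2 P(1-P))$. Note the
  conversion factor *decreases* as the prevalence $K$ decreases at fixed
  case fraction (since $z \approx K t$ for small $K$).
* Degenerate inputs fail loudly and early: empty pools name the pool,
  zero-variance scores refuse to standardize, zero cells refuse a
  continuity correction unless asked.

## Interfaces

Everything is callable as plain R functions, and `run_pipeline()` ties
the stages together from a flat key-value configuration (file or list),
writing provenance-stamped TSV outputs (package version, seed, config
hash). File formats are tab-separated text throughout; summary-statistics
readers accept combined `OR(95%CI)` cells and both `1.15E-15` and
`1.15x10^-15` notation dialects.
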