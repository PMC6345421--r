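test_that("genotypes follow Hardy-Weinberg proportions", {
  n <- 1e5
  panel <- locus_panel(c("a", "b"), c("A", "C"), c("G", "T"),
                       eaf = c(0.5, 0.2), beta = c(0, 0))
  g <- simulate_genotypes(panel, n, seed = 11)
  expect_true(all(g %in% 0:2))
  # mean dosage = 2 * eaf within 4 binomial SDs
  se <- sqrt(2 * 0.5 * 0.5 / n)
  expect_lt(abs(mean(g[, 1]) - 1), 4 * se)
  # genotype class frequencies at eaf 0.2: (0.64, 0.32, 0.04), 5 SDs
  freq <- tabulate(g[, 2] + 1L, 3L) / n
  hwe <- c(0.64, 0.32, 0.04)
  expect_true(all(abs(freq - hwe) < 5 * sqrt(hwe * (1 - hwe) / n)))
})

test_that("boundary allele frequencies are rejected", {
  panel <- data.frame(snp_id = "a", effect_allele = "A",
                      other_allele = "G", eaf = 0, beta = 0)
  expect_error(simulate_genotypes(panel, 10), "strictly")
})

test_that("phenotype is standardized: mean 0, variance 1", {
  n <- 2e5
  panel <- generate_panel(97, beta_scale = 0.03, seed = 5)
  g <- simulate_genotypes(panel, n, seed = 6)
  y <- simulate_phenotype(g, panel, seed = 7)
  expect_lt(abs(mean(y)), 0.01)
  expect_gt(var(y), 0.98)
  expect_lt(var(y), 1.02)
  # null panel: pure standard Gaussian noise
  panel0 <- locus_panel("a", "A", "G", eaf = 0.3, beta = 0)
  g0 <- simulate_genotypes(panel0, n, seed = 8)
  y0 <- simulate_phenotype(g0, panel0, seed = 9)
  expect_lt(abs(var(y0) - 1), 0.02)
})

test_that("a panel with genetic variance >= 1 is rejected", {
  panel <- locus_panel("a", "A", "G", eaf = 0.5, beta = 1.5)
  g <- simulate_genotypes(panel, 10, seed = 1)
  expect_error(simulate_phenotype(g, panel), "residual variance")
})

test_that("lower-tail truncation removes the expected fraction", {
  set.seed(21)
  y <- rnorm(1e6)
  keep <- truncate_lower_tail(y, -3)
  removed <- 1 - length(keep) / length(y)
  expect_lt(abs(removed - pnorm(-3)), 4 * sqrt(pnorm(-3) / 1e6) + 2e-4)
  expect_true(all(diff(keep) > 0))  # order preserved
  # no-op and degenerate limits
  expect_identical(truncate_lower_tail(y[1:100], -100), 1:100)
  expect_error(truncate_lower_tail(c(-1, 0), 10), "every individual")
})

test_that("extreme sampling yields disjoint cohorts of exact sizes", {
  design <- scale_design(cohort_design(), n = 5e4)
  set.seed(31)
  y <- rnorm(design$n_individuals)
  y <- y[truncate_lower_tail(y, design$truncation_sd)]
  a <- sample_extreme_cohort(y, design, seed = 32)
  counts <- table(a$labels)
  expect_equal(unname(counts[["thin"]]), design$n_thin)
  expect_equal(unname(counts[["control"]]), design$n_controls)
  expect_equal(unname(counts[["obese"]]), design$n_cases)
  # pool geometry: obese above controls above thin
  expect_gt(min(y[a$labels == "obese"]), max(y[a$labels == "control"]))
  expect_gt(min(y[a$labels == "control"]), max(y[a$labels == "thin"]))
  # determinism
  b <- sample_extreme_cohort(y, design, seed = 32)
  expect_identical(a$labels, b$labels)
})

test_that("empirical top tail threshold matches the Gaussian quantile", {
  set.seed(41)
  y <- rnorm(1e6)  # untruncated
  design <- cohort_design()
  a <- sample_extreme_cohort(y, design, seed = 42)
  expect_lt(abs(a$cutpoints[["obese_min"]] - qnorm(0.9985)), 0.05)
})

test_that("default design pools at full scale cover the requested sizes", {
  design <- cohort_design()
  set.seed(51)
  panel <- locus_panel("a", "A", "G", eaf = 0.4, beta = 0.05)
  g <- simulate_genotypes(panel, design$n_individuals)
  y <- simulate_phenotype(g, panel)
  y <- y[truncate_lower_tail(y, design$truncation_sd)]
  a <- sample_extreme_cohort(y, design)
  expect_gte(a$pool_sizes[["obese"]], design$n_cases)
  expect_gte(a$pool_sizes[["thin"]], design$n_thin)
})

test_that("undersized pools fail with the pool named", {
  design <- cohort_design()  # requests 1456 cases from a tiny sample
  set.seed(61)
  y <- rnorm(1000)
  expect_error(sample_extreme_cohort(y, design), "obese")
})

test_that("overlapping tail definitions are rejected at construction", {
  expect_error(cohort_design(upper_tail_fraction = 0.5,
                             lower_tail_fraction = 0.5,
                             control_band = c(0.5, 0.9)),
               "obese and control")
  expect_error(cohort_design(control_band = c(0.01, 0.75)),
               "thin and control")
})

test_that("asymmetric tails shift allele frequencies asymmetrically", {
  # For beta > 0 the obese tail (top 0.15%) is more extreme than the thin
  # tail (bottom 2.8%), so EAF(obese) - EAF(control) should exceed
  # EAF(control) - EAF(thin) on average.
  panel <- locus_panel("a", "A", "G", eaf = 0.4, beta = 0.08)
  design <- scale_design(cohort_design(), n = 2e5)
  set.seed(71)
  diffs <- replicate(10, {
    g <- simulate_genotypes(panel, design$n_individuals)
    y <- simulate_phenotype(g, panel)
    keep <- truncate_lower_tail(y, design$truncation_sd)
    a <- sample_extreme_cohort(y[keep], design)
    eaf <- vapply(c("thin", "control", "obese"), function(lab) {
      allele_frequency(g[keep, 1][a$labels == lab])
    }, numeric(1))
    c(upper = eaf[["obese"]] - eaf[["control"]],
      lower = eaf[["control"]] - eaf[["thin"]])
  })
  expect_gt(mean(diffs["upper", ]), mean(diffs["lower", ]))
  expect_gt(mean(diffs["lower", ]), 0)
})
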