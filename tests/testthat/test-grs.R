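test_that("GRS is the weighted dosage sum, standardized with n-1", {
  grs <- compute_grs(matrix(c(0, 1, 2), ncol = 1), weights = 0.1)
  expect_equal(grs$raw, c(0, 0.1, 0.2))
  expect_equal(grs$standardized, c(-1, 0, 1))
  # standardized invariants
  d <- matrix(rbinom(400, 2, 0.4), ncol = 4)
  w <- c(0.1, -0.2, 0.05, 0.3)
  g2 <- compute_grs(d, w)
  expect_lt(abs(mean(g2$standardized)), 1e-10)
  expect_lt(abs(sd(g2$standardized) - 1), 1e-10)
  # location invariance: adding a constant to raw leaves standardized alone
  shifted <- compute_grs(cbind(d, 2), c(w, 5))
  expect_equal(shifted$standardized, g2$standardized, tolerance = 1e-10)
  expect_error(compute_grs(d, c(0, 0, 0, 0)), "zero variance")
  expect_error(compute_grs(d, w[1:2]), "match")
})

test_that("intercept-only cumulative logit has closed-form cutpoints", {
  y <- rep(c("thin", "control", "obese"), times = c(25, 50, 25))
  fit <- fit_ordinal(NULL, y)
  expect_equal(unname(fit$cutpoints), qlogis(c(0.25, 0.75)),
               tolerance = 1e-4)
  expect_equal(fit$n_par, 2)
})

test_that("proportional-odds fit agrees with MASS::polr", {
  skip_if_not_installed("MASS")
  set.seed(111)
  dat <- simulate_po_data(500, alpha = c(-1, 1), beta = 1)
  fit <- fit_ordinal(dat$x, dat$y)
  ref <- MASS::polr(factor(dat$y, levels = c("thin", "control", "obese"),
                           ordered = TRUE) ~ dat$x)
  expect_equal(unname(fit$cutpoints), unname(ref$zeta), tolerance = 1e-3)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("fit agrees with a brute-force grid-search oracle", {
  set.seed(121)
  dat <- simulate_po_data(60, alpha = c(-0.8, 0.9), beta = 0.7)
  fit <- fit_ordinal(dat$x, dat$y)
  y_int <- as.integer(factor(dat$y, levels = c("thin", "control", "obese")))
  oracle <- oracle_clm_grid(dat$x, y_int)
  expect_equal(unname(fit$cutpoints[1]), oracle$a1, tolerance = 1e-3)
  expect_equal(unname(fit$cutpoints[2]), oracle$a2, tolerance = 1e-3)
  expect_equal(fit$coefficients$estimate, oracle$b, tolerance = 1e-3)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
})

test_that("relaxing proportionality never lowers the likelihood", {
  set.seed(131)
  for (i in 1:5) {
    dat <- simulate_po_data(300, alpha = c(-1, 1), beta = runif(1, -1, 1))
    fe <- fit_ordinal(dat$x, dat$y, mode = "proportional")
    ff <- fit_ordinal(dat$x, dat$y, mode = "partial")
    expect_gte(ff$loglik, fe$loglik - 1e-8)
    lrt <- equal_odds_lrt(fe, ff)
    expect_gte(lrt$statistic, 0)
    expect_equal(lrt$df, 1)
  }
})

test_that("partial mode varies only the designated terms", {
  set.seed(141)
  dat <- simulate_po_data(400)
  cov <- data.frame(pc1 = rnorm(400), pc2 = rnorm(400))
  fit <- fit_ordinal(dat$x, dat$y, covariates = cov, mode = "partial",
                     varying_covariates = "pc2")
  expect_setequal(fit$varying, c("score", "pc2"))
  co <- fit$coefficients
  expect_equal(sort(unique(co$cutpoint[co$term == "pc1"])), "shared")
  expect_equal(length(co$estimate[co$term == "score"]), 2)
  # full mode varies everything
  full <- fit_ordinal(dat$x, dat$y, covariates = cov, mode = "full")
  expect_gte(full$loglik, fit$loglik - 1e-8)
  expect_equal(full$n_par, 2 + 3 * 2)
})

test_that("equal-odds LRT rejects non-nested or mismatched inputs", {
  set.seed(151)
  dat <- simulate_po_data(200)
  fe <- fit_ordinal(dat$x, dat$y)
  ff <- fit_ordinal(dat$x, dat$y, mode = "partial")
  expect_error(equal_odds_lrt(ff, fe), "more parameters")
  dat2 <- simulate_po_data(200)
  fe2 <- fit_ordinal(dat2$x, dat2$y)
  expect_error(equal_odds_lrt(fe2, ff), "same data")
})

test_that("LRT under a truly shared coefficient stays a valid chi-square", {
  set.seed(161)
  dat <- simulate_po_data(200, beta = 0)
  fe <- fit_ordinal(dat$x, dat$y, mode = "proportional")
  ff <- fit_ordinal(dat$x, dat$y, mode = "partial")
  lrt <- equal_odds_lrt(fe, ff)
  expect_gte(lrt$p_value, 0)
  expect_lte(lrt$p_value, 1)
})

test_that("simulation p-values count strict exceedances", {
  expect_equal(grs_simulation_pvalue(5, c(1, 2, 3, 4))$empirical_p, 0)
  expect_equal(grs_simulation_pvalue(5, c(1, 2, 3, 4))$p_label, "< 1/4")
  expect_equal(grs_simulation_pvalue(0, c(1, 2, 3, 4))$empirical_p, 1)
  expect_equal(grs_simulation_pvalue(2.5, c(1, 2, 3, 4))$empirical_p, 0.5)
  expect_error(grs_simulation_pvalue(1, c(2)), "at least 2")
})

test_that("mean-GRS category test is a one-sample t against sim means", {
  eq <- mean_grs_category_test(1.0, c(0.9, 1.0, 1.1))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  res <- mean_grs_category_test(1.2, c(0.9, 1.0, 1.1))
  expect_equal(res$statistic, 2.0, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-2, 2), tolerance = 1e-12)
  expect_error(mean_grs_category_test(1, c(1, 1, 1)), "zero spread")
})

test_that("extreme cohorts recover a positive, variance-ordered GRS effect", {
  # proportional-odds score coefficient should be positive and grow with
  # the panel's genetic variance
  design <- scale_design(cohort_design(), n = 1e5, n_replicates = 1)
  coefs <- vapply(c(0.02, 0.08), function(bscale) {
    panel <- locus_panel(paste0("s", 1:10), rep("A", 10), rep("G", 10),
                         eaf = rep(0.4, 10), beta = rep(bscale, 10))
    set.seed(171)
    g <- simulate_genotypes(panel, design$n_individuals)
    y <- simulate_phenotype(g, panel)
    keep <- truncate_lower_tail(y, design$truncation_sd)
    a <- sample_extreme_cohort(y[keep], design)
    assigned <- which(a$labels != "unassigned")
    grs <- compute_grs(g[keep, , drop = FALSE][assigned, , drop = FALSE],
                       panel$beta)
    fit <- fit_ordinal(grs, droplevels(a$labels[assigned]))
    fit$coefficients$estimate
  }, numeric(1))
  expect_true(all(coefs > 0))
  expect_gt(coefs[2], coefs[1])
})
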