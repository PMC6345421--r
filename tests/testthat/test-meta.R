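test_that("direction-consistency binomial test is exact", {
  # k = n collapses to 0.5^n
  for (n in c(1, 5, 11, 15, 40)) {
    expect_equal(binomial_consistency_test(n, n), 0.5^n, tolerance = 1e-12)
  }
  expect_equal(binomial_consistency_test(1, 1), 0.5)
  # partial consistency: exact upper-tail summation
  expect_equal(binomial_consistency_test(7, 10),
               sum(dbinom(7:10, 10, 0.5)), tolerance = 1e-12)
  expect_equal(binomial_consistency_test(0, 10), 1)
  expect_error(binomial_consistency_test(11, 10), "k_consistent")
})

test_that("count_consistent_nominal harmonizes alleles before counting", {
  discovery <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "C", "G", "A"),
    other_allele = c("G", "T", "T", "C"),
    log_or = c(0.2, 0.3, -0.1, 0.25)
  )
  # rs1 same frame, consistent; rs2 allele-swapped with inverted OR (still
  # consistent after harmonization); rs3 opposite direction; rs4 not
  # nominally significant in the reference
  reference <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "T", "G", "A"),
    other_allele = c("G", "C", "T", "C"),
    log_or = c(0.15, -0.22, 0.3, 0.5),
    p_value = c(0.01, 0.001, 0.04, 0.5)
  )
  res <- count_consistent_nominal(discovery, reference)
  expect_equal(res$n, 3)
  expect_equal(res$k, 2)
  # strand-flipped record (G/T reported as C/A) still harmonizes
  ref2 <- reference
  ref2$effect_allele[3] <- "C"
  ref2$other_allele[3] <- "A"
  res2 <- count_consistent_nominal(discovery, ref2)
  expect_equal(res2$n, 3)
  # irresolvable allele pair is excluded with a warning
  ref3 <- reference
  ref3$effect_allele[1] <- "T"
  expect_warning(res3 <- count_consistent_nominal(discovery, ref3), "rs1")
  expect_equal(res3$excluded, "rs1")
  expect_equal(res3$n, 2)
})

test_that("fixed-effect meta is the inverse-variance combination", {
  # single study: identity
  one <- data.frame(or = 1.5, ci_low = 1.2, ci_high = 1.875)
  m1 <- fixed_effect_meta(one)
  expect_equal(m1$or, 1.5, tolerance = 1e-12)
  expect_equal(m1$se, se_from_ci(1.5, 1.2, 1.875), tolerance = 1e-12)
  expect_true(is.na(m1$q))
  # combined estimate lies inside the study estimates and tightens the SE
  two <- data.frame(or = c(2.37, 1.54), ci_low = c(1.75, 1.35),
                    ci_high = c(3.20, 1.76))
  m2 <- fixed_effect_meta(two)
  expect_gt(m2$log_or, log(1.54))
  expect_lt(m2$log_or, log(2.37))
  expect_lt(m2$se, min(se_from_ci(2.37, 1.75, 3.20),
                       se_from_ci(1.54, 1.35, 1.76)))
  expect_error(fixed_effect_meta(data.frame()), "no studies")
})

test_that("fixed-effect meta matches metafor on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(181)
  for (i in 1:3) {
    k <- sample(2:5, 1)
    yi <- rnorm(k, 0.3, 0.2)
    sei <- runif(k, 0.05, 0.3)
    mine <- fixed_effect_meta(data.frame(log_or = yi, se_log_or = sei))
    ref <- metafor::rma(yi = yi, sei = sei, method = "FE")
    expect_equal(mine$log_or, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$q, ref$QE, tolerance = 1e-10)
    expect_equal(mine$p_value, ref$pval, tolerance = 1e-8)
  }
})

test_that("Cochran's Q detects the printed two-study heterogeneity", {
  # discovery vs replication pair with visibly different ORs
  pair <- data.frame(or = c(2.37, 1.54), ci_low = c(1.75, 1.35),
                     ci_high = c(3.20, 1.76))
  q <- cochran_q(pair)
  expect_equal(q$q, 6.5, tolerance = 0.02)
  expect_true(q$p_value > 0.009 && q$p_value < 0.012)
  # identical studies: Q = 0, p = 1
  dup <- data.frame(log_or = c(0.4, 0.4), se_log_or = c(0.1, 0.1))
  q0 <- cochran_q(dup)
  expect_equal(q0$q, 0)
  expect_equal(q0$p_value, 1)
  # invariant under study reordering
  expect_equal(cochran_q(pair[2:1, ])$q, q$q, tolerance = 1e-12)
  expect_error(cochran_q(pair[1, ]), "at least 2")
})

test_that("replication decision applies the three criteria jointly", {
  disc <- data.frame(or = 2.37, ci_low = 1.75, ci_high = 3.20)
  reps <- data.frame(or = 1.54, ci_low = 1.35, ci_high = 1.76,
                     p_value = 3.57e-10)
  meta <- fixed_effect_meta(rbind(disc[, 1:3],
                                  reps[, c("or", "ci_low", "ci_high")]))
  dec <- replication_decision(disc, reps, meta)
  expect_true(dec$direction_consistent)
  expect_true(dec$replication_nominal)
  expect_true(dec$meta_genomewide)
  expect_true(dec$replicated)
  # opposite replication direction fails
  flip <- transform(reps, or = 1 / or, ci_low = 1 / 1.76,
                    ci_high = 1 / 1.35)
  dec2 <- replication_decision(disc, flip, meta)
  expect_false(dec2$direction_consistent)
  expect_false(dec2$replicated)
  # meta p at the threshold boundary
  weak <- structure(list(log_or = 0.1, se = 0.1 / qnorm(1 - 3e-8),
                         or = exp(0.1), ci_low = 1, ci_high = 1.3,
                         p_value = 6e-8, n_studies = 2, q = 0, q_df = 1,
                         q_p = 1), class = "meta_result")
  dec3 <- replication_decision(disc, reps, weak)
  expect_false(dec3$replicated)
  dec4 <- replication_decision(disc, reps, weak, gw_threshold = 1e-7)
  expect_true(dec4$replicated)
  # stricter threshold for denser variant sets
  dec5 <- replication_decision(disc, reps, meta, gw_threshold = 1.17e-8)
  expect_equal(dec5$meta_genomewide, meta$p_value < 1.17e-8)
})
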