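# Independent oracles used across the suite. These never call the package
# code paths they are used to check.

# Liability-model oracle for a single biallelic locus under the additive
# model with lower-tail truncation and percentile-defined sampling regions.
# Computes, by numerical integration over the three-component Gaussian
# mixture (one component per genotype), the expected effect-allele
# frequency in each sampling region and the implied allelic odds ratios.
liability_tail_oracle <- function(eaf, beta, design) {
  p <- eaf
  pg <- dbinom(0:2, 2, p)
  mu <- beta * ((0:2) - 2 * p)
  sig <- sqrt(1 - 2 * p * (1 - p) * beta^2)
  F_mix <- function(t) sum(pg * pnorm(t, mu, sig))
  t0 <- design$truncation_sd
  F0 <- F_mix(t0)
  F_tr <- function(t) (F_mix(t) - F0) / (1 - F0)
  q_tr <- function(q) uniroot(function(t) F_tr(t) - q, c(-20, 20),
                              tol = 1e-12)$root
  thr <- list(
    thin_hi = q_tr(design$lower_tail_fraction),
    band_lo = q_tr(design$control_band[1]),
    band_hi = q_tr(design$control_band[2]),
    obese_lo = q_tr(1 - design$upper_tail_fraction)
  )
  region_eaf <- function(a, b) {
    mass <- pg * (pnorm(b, mu, sig) - pnorm(a, mu, sig))
    sum((0:2) / 2 * mass) / sum(mass)
  }
  eafs <- c(
    thin = region_eaf(t0, thr$thin_hi),
    control = region_eaf(thr$band_lo, thr$band_hi),
    obese = region_eaf(thr$obese_lo, Inf)
  )
  odds <- function(f) f / (1 - f)
  list(
    eaf = eafs,
    or_case_vs_control = odds(eafs[["obese"]]) / odds(eafs[["control"]]),
    or_control_vs_thin = odds(eafs[["control"]]) / odds(eafs[["thin"]])
  )
}

# Independent cumulative-logit log-likelihood (direct category
# probabilities; written without reference to the package internals).
# y: integer category codes 1..3, proportional model with one predictor.
oracle_clm_loglik <- function(a1, a2, b, x, y) {
  if (a2 <= a1) return(-Inf)
  g1 <- plogis(a1 - b * x)
  g2 <- plogis(a2 - b * x)
  pr <- cbind(g1, g2 - g1, 1 - g2)
  p_i <- pr[cbind(seq_along(y), y)]
  if (any(p_i <= 0)) return(-Inf)
  sum(log(p_i))
}

# Brute-force maximization of the three-parameter proportional cumulative
# logit by iterative grid refinement.
oracle_clm_grid <- function(x, y, center = c(-1, 1, 0), span = 3,
                            n_grid = 13L, rounds = 7L) {
  best <- c(center, ll = oracle_clm_loglik(center[1], center[2], center[3],
                                           x, y))
  for (round in seq_len(rounds)) {
    a1s <- seq(best[1] - span, best[1] + span, length.out = n_grid)
    a2s <- seq(best[2] - span, best[2] + span, length.out = n_grid)
    bs <- seq(best[3] - span, best[3] + span, length.out = n_grid)
    for (a1 in a1s) for (a2 in a2s) for (b in bs) {
      ll <- oracle_clm_loglik(a1, a2, b, x, y)
      if (ll > best[4]) best <- c(a1, a2, b, ll)
    }
    span <- span * 0.35
  }
  list(a1 = best[1], a2 = best[2], b = best[3], loglik = best[4])
}

# Brute-force Bernoulli likelihood maximization on a grouped binary
# dataset: per-group success probabilities on an iteratively refined grid
# (full model) and one common probability (null model).
oracle_bernoulli_loglik <- function(successes, totals) {
  ll_one <- function(p, k, m) k * log(p) + (m - k) * log(1 - p)
  max_one <- function(k, m) {
    lo <- 1e-9
    hi <- 1 - 1e-9
    best <- c(p = 0.5, ll = ll_one(0.5, k, m))
    for (round in 1:8) {
      ps <- seq(lo, hi, length.out = 101)
      lls <- ll_one(ps, k, m)
      i <- which.max(lls)
      if (lls[i] > best[2]) best <- c(ps[i], lls[i])
      width <- (hi - lo) / 10
      lo <- max(1e-12, best[1] - width)
      hi <- min(1 - 1e-12, best[1] + width)
    }
    unname(best[2])
  }
  list(
    loglik_full = sum(mapply(max_one, successes, totals)),
    loglik_null = max_one(sum(successes), sum(totals))
  )
}

# Simulate ordinal categories from a proportional-odds model.
simulate_po_data <- function(n, alpha = c(-1, 1), beta = 1) {
  x <- rnorm(n)
  u <- runif(n)
  g1 <- plogis(alpha[1] - beta * x)
  g2 <- plogis(alpha[2] - beta * x)
  y <- ifelse(u < g1, "thin", ifelse(u < g2, "control", "obese"))
  list(x = x, y = y)
}
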