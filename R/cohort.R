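#' Cohort design for asymmetric extreme sampling
#'
#' Encodes the ascertainment scheme of an extreme-sampling case-control
#' study of the BMI distribution: severely obese cases from the top
#' \code{upper_tail_fraction} (default 0.15%, the population prevalence of
#' childhood-onset severe obesity), persistently thin cases from the bottom
#' \code{lower_tail_fraction} (default 2.8%, the primary-care prevalence of
#' BMI <= 19), and controls from a non-extreme percentile band
#' (default (2.8%, 75%], emulating a BMI 19-30 band). Percentiles are taken
#' on the phenotype distribution after lower-tail truncation at
#' \code{truncation_sd} (default -3 SD: phenotypes that extreme are not
#' compatible with healthy human life, so the realized BMI distribution has
#' a shorter lower tail).
#'
#' @param n_replicates number of simulation replicates for ensemble runs.
#' @param n_individuals simulated population size per replicate.
#' @param truncation_sd lower truncation threshold, SD units.
#' @param upper_tail_fraction fraction of the (truncated) distribution
#'   defining the obese pool.
#' @param lower_tail_fraction fraction defining the thin pool.
#' @param control_band length-2 fractions (low, high]: the control
#'   percentile band.
#' @param n_cases,n_thin,n_controls sampled cohort sizes.
#' @param seed optional master seed recorded with the design.
#' @return A list of class \code{cohort_design}.
#' @examples
#' design <- cohort_design()
#' design$upper_tail_fraction
#' @export
cohort_design <- function(n_replicates = 10000L,
                          n_individuals = 1e6,
                          truncation_sd = -3,
                          upper_tail_fraction = 0.0015,
                          lower_tail_fraction = 0.028,
                          control_band = c(0.028, 0.75),
                          n_cases = 1456L,
                          n_thin = 1471L,
                          n_controls = 6460L,
                          seed = NULL) {
  check_number(n_replicates, "n_replicates", lower = 1, integer = TRUE)
  check_number(n_individuals, "n_individuals", lower = 1, integer = TRUE)
  check_number(truncation_sd, "truncation_sd")
  check_fraction(upper_tail_fraction, "upper_tail_fraction")
  check_fraction(lower_tail_fraction, "lower_tail_fraction")
  if (length(control_band) != 2L || !is.numeric(control_band) ||
      any(control_band <= 0) || any(control_band >= 1) ||
      control_band[1] >= control_band[2]) {
    stop("`control_band` must be two increasing fractions in (0, 1)",
         call. = FALSE)
  }
  if (control_band[1] < lower_tail_fraction) {
    stop("control_band must start at or above lower_tail_fraction ",
         "(overlapping thin and control pools)", call. = FALSE)
  }
  if (control_band[2] > 1 - upper_tail_fraction) {
    stop("control_band must end at or below 1 - upper_tail_fraction ",
         "(overlapping obese and control pools)", call. = FALSE)
  }
  check_number(n_cases, "n_cases", lower = 1, integer = TRUE)
  check_number(n_thin, "n_thin", lower = 1, integer = TRUE)
  check_number(n_controls, "n_controls", lower = 1, integer = TRUE)
  structure(list(
    n_replicates = as.integer(n_replicates),
    n_individuals = as.integer(n_individuals),
    truncation_sd = truncation_sd,
    upper_tail_fraction = upper_tail_fraction,
    lower_tail_fraction = lower_tail_fraction,
    control_band = as.numeric(control_band),
    n_cases = as.integer(n_cases),
    n_thin = as.integer(n_thin),
    n_controls = as.integer(n_controls),
    seed = seed
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    paste0("Extreme-sampling cohort design\n",
           "  replicates: %d, individuals per replicate: %d\n",
           "  lower truncation: %g SD\n",
           "  obese: top %.4g%% (n = %d); thin: bottom %.4g%% (n = %d)\n",
           "  controls: (%.4g%%, %.4g%%] band (n = %d)\n"),
    x$n_replicates, x$n_individuals, x$truncation_sd,
    100 * x$upper_tail_fraction, x$n_cases,
    100 * x$lower_tail_fraction, x$n_thin,
    100 * x$control_band[1], 100 * x$control_band[2], x$n_controls))
  invisible(x)
}

#' Rescale a cohort design to a smaller simulated population
#'
#' Shrinks \code{n_individuals} to \code{n} and the three cohort sizes by
#' the same factor (using \code{floor}, so sampled cohorts never exceed the
#' shrunken eligible pools). Tail fractions, band, and truncation are kept,
#' so the ascertainment geometry - and therefore the asymmetry between the
#' obese and thin contrasts - is preserved at reduced cost.
#'
#' @param design a \code{\link{cohort_design}}.
#' @param n new population size per replicate.
#' @param n_replicates optional new replicate count.
#' @return A rescaled \code{\link{cohort_design}}.
#' @examples
#' scale_design(cohort_design(), n = 1e5)
#' @export
scale_design <- function(design, n, n_replicates = design$n_replicates) {
  stopifnot(inherits(design, "cohort_design"))
  check_number(n, "n", lower = 1, integer = TRUE)
  s <- n / design$n_individuals
  cohort_design(
    n_replicates = n_replicates,
    n_individuals = n,
    truncation_sd = design$truncation_sd,
    upper_tail_fraction = design$upper_tail_fraction,
    lower_tail_fraction = design$lower_tail_fraction,
    control_band = design$control_band,
    n_cases = max(1L, floor(design$n_cases * s)),
    n_thin = max(1L, floor(design$n_thin * s)),
    n_controls = max(1L, floor(design$n_controls * s)),
    seed = design$seed
  )
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each genotype is the count of the effect allele from two independent
#' allele draws with probability \code{eaf}, i.e.
#' \code{Binomial(2, eaf)}: genotype class frequencies
#' \eqn{(1-p)^2, 2p(1-p), p^2}. Loci are independent (linkage
#' equilibrium).
#'
#' @param panel a \code{\link{locus_panel}}.
#' @param n number of individuals.
#' @param seed optional seed; \code{NULL} draws from the current RNG stream.
#' @return An integer matrix (n x loci) with entries in \{0, 1, 2\} and
#'   locus ids as column names.
#' @examples
#' g <- simulate_genotypes(generate_panel(5, seed = 1), n = 100, seed = 2)
#' table(g[, 1])
#' @export
simulate_genotypes <- function(panel, n, seed = NULL) {
  panel <- validate_panel(panel)
  check_number(n, "n", lower = 1, integer = TRUE)
  m <- nrow(panel)
  with_seed(seed, {
    g <- matrix(rbinom(n * m, 2L, rep(panel$eaf, each = n)),
                nrow = n, ncol = m,
                dimnames = list(NULL, panel$snp_id))
    storage.mode(g) <- "integer"
    g
  })
}

#' Simulate a standardized additive phenotype
#'
#' \deqn{y_i = \sum_j \beta_j (g_{ij} - 2 p_j) + \epsilon_i,\qquad
#'       \epsilon_i \sim N(0,\, 1 - \sum_j 2 p_j (1 - p_j) \beta_j^2)}
#' Genotypes are centered at their expectation so the phenotype has mean 0,
#' and the residual variance is scaled so the total variance is 1:
#' effect sizes are interpreted in phenotype-SD units, matching
#' standardized GWAS effect estimates.
#'
#' @param genotypes matrix from \code{\link{simulate_genotypes}} (columns
#'   must match the panel's locus order).
#' @param panel the \code{\link{locus_panel}} used to simulate
#'   \code{genotypes}.
#' @param seed optional seed for the residual draw.
#' @return Numeric vector of phenotypes in SD units.
#' @export
simulate_phenotype <- function(genotypes, panel, seed = NULL) {
  panel <- validate_panel(panel)
  if (!is.matrix(genotypes) || ncol(genotypes) != nrow(panel)) {
    stop("`genotypes` must be a matrix with one column per panel locus",
         call. = FALSE)
  }
  if (!is.null(colnames(genotypes)) &&
      !identical(colnames(genotypes), panel$snp_id)) {
    stop("genotype columns do not match the panel locus order",
         call. = FALSE)
  }
  g_var <- genetic_variance(panel)
  if (g_var >= 1) {
    stop(sprintf(
      "panel genetic variance (%.3f) leaves no residual variance; betas are in SD units and must imply genetic variance < 1",
      g_var), call. = FALSE)
  }
  n <- nrow(genotypes)
  genetic <- drop(genotypes %*% panel$beta) - sum(2 * panel$eaf * panel$beta)
  with_seed(seed, genetic + rnorm(n, 0, sqrt(1 - g_var)))
}

#' Remove the lower tail of a phenotype
#'
#' Returns the indices of individuals whose phenotype is at or above
#' \code{threshold_sd}; individuals below the threshold are removed. Used
#' to emulate the shortened lower tail of the realized BMI distribution
#' before extreme sampling.
#'
#' @param phenotype numeric phenotype vector.
#' @param threshold_sd truncation threshold, SD units.
#' @return Integer vector of retained indices, in the original order.
#' @examples
#' truncate_lower_tail(c(-4, -1, 0, 2), threshold_sd = -3)
#' @export
truncate_lower_tail <- function(phenotype, threshold_sd = -3) {
  check_number(threshold_sd, "threshold_sd")
  y <- as.numeric(phenotype)
  keep <- which(y >= threshold_sd)
  if (length(keep) == 0L) {
    stop("lower-tail truncation removed every individual", call. = FALSE)
  }
  keep
}

#' Sample an asymmetric extreme case-control cohort
#'
#' Assigns cohort labels by empirical order statistics of the (already
#' truncated) phenotype: the obese pool is the top
#' \code{upper_tail_fraction}, the thin pool the bottom
#' \code{lower_tail_fraction}, and the control pool the
#' \code{control_band} percentile interval. The requested numbers of
#' cases, thin individuals, and controls are then drawn uniformly without
#' replacement from their pools. Ties in the phenotype are broken by
#' stable index order.
#'
#' @param phenotype numeric phenotype vector (post-truncation).
#' @param design a \code{\link{cohort_design}}.
#' @param seed optional seed for the within-pool draws.
#' @return An object of class \code{cohort_assignment}: a list with
#'   \code{labels} (factor of \code{thin}/\code{control}/\code{obese}/
#'   \code{unassigned} per individual), pool sizes, and the phenotype
#'   cut points realized by the pools.
#' @export
sample_extreme_cohort <- function(phenotype, design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  y <- as.numeric(phenotype)
  n <- length(y)
  if (n < 1L) stop("empty phenotype vector", call. = FALSE)
  r <- rank(y, ties.method = "first")

  k_thin <- floor(design$lower_tail_fraction * n)
  k_obese <- floor(design$upper_tail_fraction * n)
  band_lo <- floor(design$control_band[1] * n) # exclusive lower rank
  band_hi <- floor(design$control_band[2] * n) # inclusive upper rank

  thin_pool <- which(r <= k_thin)
  obese_pool <- which(r > n - k_obese)
  control_pool <- which(r > band_lo & r <= band_hi)

  pools <- c(thin = length(thin_pool), control = length(control_pool),
             obese = length(obese_pool))
  wanted <- c(thin = design$n_thin, control = design$n_controls,
              obese = design$n_cases)
  short <- names(wanted)[pools < wanted]
  if (length(short)) {
    stop(sprintf(
      "eligible pool smaller than requested sample: %s",
      paste(sprintf("%s (pool %d < requested %d)", short,
                    pools[short], wanted[short]), collapse = "; ")),
      call. = FALSE)
  }

  labels <- with_seed(seed, {
    lab <- factor(rep("unassigned", n),
                  levels = c("thin", "control", "obese", "unassigned"))
    lab[sample(thin_pool, design$n_thin)] <- "thin"
    lab[sample(control_pool, design$n_controls)] <- "control"
    lab[sample(obese_pool, design$n_cases)] <- "obese"
    lab
  })

  structure(list(
    labels = labels,
    n = n,
    pool_sizes = pools,
    sample_sizes = wanted,
    cutpoints = c(
      thin_max = if (k_thin) max(y[thin_pool]) else NA_real_,
      control_min = min(y[control_pool]),
      control_max = max(y[control_pool]),
      obese_min = if (k_obese) min(y[obese_pool]) else NA_real_
    )
  ), class = "cohort_assignment")
}

#' @export
print.cohort_assignment <- function(x, ...) {
  cat("Extreme-sampled cohort assignment\n")
  print(table(x$labels))
  cat("pool sizes:", paste(names(x$pool_sizes), x$pool_sizes,
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}
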