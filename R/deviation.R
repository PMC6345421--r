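# Ensemble simulation under the additive model and the empirical
# deviation-from-additivity test.

# Contrast names, in the order stored in ensemble arrays. Both contrasts
# are reported with the lower-BMI group as reference:
#   case_vs_control  = obese vs controls
#   control_vs_thin  = controls vs thin
CONTRASTS <- c("case_vs_control", "control_vs_thin")

# Allelic OR per locus between two index sets of a genotype matrix.
# Ensemble replicates at desk scale can produce zero allele counts at rare
# loci; those tables get the Haldane-Anscombe correction so every replicate
# contributes a finite OR (observed and simulated draws are treated
# identically, so rank-based empirical p-values stay exchangeable).
contrast_or <- function(genotypes, idx1, idx0) {
  a <- colSums(genotypes[idx1, , drop = FALSE])
  b <- 2 * length(idx1) - a
  cc <- colSums(genotypes[idx0, , drop = FALSE])
  d <- 2 * length(idx0) - cc
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  if (any(zero)) {
    a[zero] <- a[zero] + 0.5
    b[zero] <- b[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5
    d[zero] <- d[zero] + 0.5
  }
  (a * d) / (b * cc)
}

# Run `fun(genotypes, phenotype, assignment, replicate)` on every simulated,
# truncated, extreme-sampled replicate. Genotypes/phenotype passed to `fun`
# are restricted to post-truncation survivors. Master seed spawns one child
# seed per replicate.
replicate_cohorts <- function(panel, design, fun,
                              n_replicates = design$n_replicates,
                              seed = design$seed, progress = FALSE) {
  panel <- validate_panel(panel)
  stopifnot(inherits(design, "cohort_design"))
  seeds <- child_seeds(seed %||% 0L, n_replicates)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    out[[r]] <- with_seed(seeds[r], {
      g <- simulate_genotypes(panel, design$n_individuals)
      y <- simulate_phenotype(g, panel)
      keep <- truncate_lower_tail(y, design$truncation_sd)
      g <- g[keep, , drop = FALSE]
      y <- y[keep]
      assignment <- sample_extreme_cohort(y, design)
      fun(g, y, assignment, r)
    })
    if (progress && r %% 50L == 0L) {
      message(sprintf("replicate %d / %d", r, n_replicates))
    }
  }
  out
}

#' Simulate the additive-model odds-ratio ensemble
#'
#' For each replicate: simulate Hardy-Weinberg genotypes and the
#' standardized additive phenotype, truncate the lower tail, sample the
#' asymmetric extreme cohort, and record the per-locus allelic odds ratios
#' for both contrasts (obese vs controls, controls vs thin; lower-BMI group
#' as reference). The resulting per-locus OR distributions form the
#' empirical null of the deviation-from-additivity test.
#'
#' @param panel a \code{\link{locus_panel}}.
#' @param design a \code{\link{cohort_design}}.
#' @param n_replicates number of replicates (defaults to the design's).
#' @param seed master seed (defaults to the design's, or 0).
#' @param progress print progress every 50 replicates.
#' @return An object of class \code{sim_ensemble}: a list with \code{ors}
#'   (array replicate x locus x contrast), \code{panel}, \code{design},
#'   and \code{seed}.
#' @examples
#' panel <- generate_panel(3, seed = 1)
#' design <- scale_design(cohort_design(), n = 2e4, n_replicates = 5)
#' ens <- run_ensemble(panel, design, seed = 1)
#' apply(ens$ors, c(2, 3), mean)
#' @export
run_ensemble <- function(panel, design,
                         n_replicates = design$n_replicates,
                         seed = design$seed, progress = FALSE) {
  panel <- validate_panel(panel)
  reps <- replicate_cohorts(panel, design, function(g, y, assignment, r) {
    lab <- assignment$labels
    obese <- which(lab == "obese")
    control <- which(lab == "control")
    thin <- which(lab == "thin")
    cbind(case_vs_control = contrast_or(g, obese, control),
          control_vs_thin = contrast_or(g, control, thin))
  }, n_replicates = n_replicates, seed = seed, progress = progress)

  ors <- array(NA_real_,
               dim = c(n_replicates, nrow(panel), 2L),
               dimnames = list(NULL, panel$snp_id, CONTRASTS))
  for (r in seq_along(reps)) ors[r, , ] <- reps[[r]]
  structure(list(ors = ors, panel = panel, design = design,
                 seed = seed %||% 0L),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf(
    "Additive-model OR ensemble: %d replicates x %d loci x 2 contrasts (seed %s)\n",
    dim(x$ors)[1], dim(x$ors)[2], format(x$seed)))
  cat("mean simulated OR by contrast:\n")
  print(round(apply(x$ors, 3, mean), 4))
  invisible(x)
}

#' Empirical p-value for deviation from additivity
#'
#' The deviation statistic is the absolute difference, on the OR scale,
#' between the observed odds ratio and the mean simulated odds ratio. The
#' empirical p-value is the fraction of simulation replicates whose own
#' deviation from the simulated mean is equal to or larger than the
#' observed deviation. A zero count is stored as 0 and rendered
#' \code{"< 1/R"}; \code{add_one = TRUE} switches to the
#' \code{(k + 1) / (R + 1)} convention for calibration work.
#'
#' @param observed_or observed odds ratio.
#' @param sim_ors numeric vector of simulated odds ratios (>= 2 draws).
#' @param add_one use the (k+1)/(R+1) estimator instead of k/R.
#' @return A list of class \code{deviation_result}: \code{observed_or},
#'   \code{sim_mean_or}, \code{abs_deviation}, \code{empirical_p},
#'   \code{p_label}, \code{n_sims}.
#' @examples
#' empirical_deviation_p(1.3, c(1.0, 1.1, 1.2, 1.3))
#' @export
empirical_deviation_p <- function(observed_or, sim_ors, add_one = FALSE) {
  check_number(observed_or, "observed_or", lower = 0, strict = TRUE)
  sims <- as.numeric(sim_ors)
  if (length(sims) < 2L) {
    stop("need at least 2 simulated draws", call. = FALSE)
  }
  if (any(!is.finite(sims)) || any(sims <= 0)) {
    stop("simulated ORs must be finite and positive", call. = FALSE)
  }
  m <- mean(sims)
  d_obs <- abs(observed_or - m)
  # "equal or larger" with a tiny relative tolerance so exact ties are not
  # lost to floating-point representation of the two subtractions
  tol <- 1e-12 * max(1, d_obs)
  k <- sum(abs(sims - m) >= d_obs - tol)
  R <- length(sims)
  p <- if (add_one) (k + 1) / (R + 1) else k / R
  structure(list(
    observed_or = observed_or,
    sim_mean_or = m,
    abs_deviation = d_obs,
    empirical_p = p,
    p_label = if (k == 0L && !add_one) sprintf("< 1/%d", R) else
      format(p, digits = 4),
    n_sims = R
  ), class = "deviation_result")
}

#' Bonferroni-corrected significance threshold
#'
#' \code{alpha / (n_loci * n_analyses)}; for 97 loci tested in two
#' contrasts at alpha = 0.05 this is 0.05 / 194, approximately 0.0002.
#'
#' @param n_loci number of loci tested.
#' @param n_analyses number of analyses (contrasts) per locus.
#' @param alpha family-wise error rate.
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(97, 2)
#' @export
bonferroni_threshold <- function(n_loci, n_analyses = 1, alpha = 0.05) {
  check_number(n_loci, "n_loci", lower = 1, integer = TRUE)
  check_number(n_analyses, "n_analyses", lower = 1, integer = TRUE)
  check_fraction(alpha, "alpha")
  alpha / (n_loci * n_analyses)
}

#' Per-locus deviation results against an ensemble
#'
#' Matches observed odds ratios to the ensemble by locus id and contrast
#' and computes each locus's empirical deviation p-value
#' (\code{\link{empirical_deviation_p}}). Observed ORs are inputs (e.g.
#' read from a summary-statistics file), never recomputed from raw data.
#'
#' @param ensemble a \code{\link{run_ensemble}} result.
#' @param observed data frame with columns \code{snp_id}, \code{contrast}
#'   (one of \code{"case_vs_control"}, \code{"control_vs_thin"}), and
#'   \code{or}.
#' @param add_one passed to \code{\link{empirical_deviation_p}}.
#' @return A data frame with one row per (locus, contrast).
#' @export
deviation_results <- function(ensemble, observed, add_one = FALSE) {
  stopifnot(inherits(ensemble, "sim_ensemble"))
  required <- c("snp_id", "contrast", "or")
  if (!all(required %in% names(observed))) {
    stop("`observed` needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!all(observed$contrast %in% CONTRASTS)) {
    stop("contrast must be one of: ", paste(CONTRASTS, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(observed$snp_id, dimnames(ensemble$ors)[[2]])
  if (length(unknown)) {
    stop("loci absent from the ensemble: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(observed)), function(i) {
    snp <- observed$snp_id[i]
    con <- observed$contrast[i]
    dev <- empirical_deviation_p(observed$or[i], ensemble$ors[, snp, con],
                                 add_one = add_one)
    data.frame(snp_id = snp, contrast = con,
               observed_or = dev$observed_or,
               sim_mean_or = dev$sim_mean_or,
               abs_deviation = dev$abs_deviation,
               empirical_p = dev$empirical_p,
               p_label = dev$p_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ranked deviation report with significance flags
#'
#' Sorts per-locus deviation results by empirical p-value and flags nominal
#' (p < 0.05) and multiple-testing-corrected significance.
#'
#' @param results data frame from \code{\link{deviation_results}}.
#' @param threshold corrected significance threshold; defaults to the
#'   Bonferroni threshold for the number of loci and contrasts present.
#' @param alpha nominal significance level.
#' @return The ranked data frame with logical columns \code{nominal} and
#'   \code{corrected}, and the threshold as attribute \code{"threshold"}.
#' @export
deviation_table <- function(results, threshold = NULL, alpha = 0.05) {
  needed <- c("snp_id", "contrast", "empirical_p")
  if (!all(needed %in% names(results))) {
    stop("`results` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(threshold)) {
    threshold <- bonferroni_threshold(length(unique(results$snp_id)),
                                      length(unique(results$contrast)),
                                      alpha)
  }
  out <- results[order(results$empirical_p), , drop = FALSE]
  out$nominal <- out$empirical_p < alpha
  out$corrected <- out$empirical_p < threshold
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}
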