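# Direction-of-effect enrichment, fixed-effect meta-analysis, Cochran's Q,
# and the three-criterion replication filter.

#' One-sided binomial test for direction-of-effect consistency
#'
#' Probability of observing \code{k_consistent} or more directionally
#' consistent signals out of \code{n_total} under the null that each
#' direction is a fair coin flip: \eqn{P(X \ge k)} for
#' \eqn{X \sim Binomial(n, 1/2)}, by exact summation. When every signal is
#' consistent (k = n) this reduces to \eqn{0.5^n}.
#'
#' @param k_consistent number of direction-consistent signals.
#' @param n_total number of signals examined.
#' @return One-sided upper-tail p-value.
#' @examples
#' binomial_consistency_test(40, 40)   # 0.5^40
#' binomial_consistency_test(15, 15)
#' @export
binomial_consistency_test <- function(k_consistent, n_total) {
  check_number(n_total, "n_total", lower = 1, integer = TRUE)
  check_number(k_consistent, "k_consistent", lower = 0, upper = n_total,
               integer = TRUE)
  pbinom(k_consistent - 1, n_total, 0.5, lower.tail = FALSE)
}

# Harmonize a reference record's effect direction onto a discovery
# record's allele frame. Returns +1 (same frame), -1 (alleles swapped:
# flip the sign), or NA (irresolvable). Strand flips (A<->T, C<->G) are
# resolved by complementing the reference alleles first.
harmonize_sign <- function(ea_d, oa_d, ea_r, oa_r) {
  comp <- function(a) chartr("ACGTacgt", "TGCAtgca", a)
  for (flip in c(FALSE, TRUE)) {
    ea <- if (flip) comp(ea_r) else ea_r
    oa <- if (flip) comp(oa_r) else oa_r
    if (identical(toupper(ea), toupper(ea_d)) &&
        identical(toupper(oa), toupper(oa_d))) return(1)
    if (identical(toupper(ea), toupper(oa_d)) &&
        identical(toupper(oa), toupper(ea_d))) return(-1)
  }
  NA_real_
}

#' Count direction-consistent, nominally significant reference signals
#'
#' Matches discovery signals to an independent reference analysis by
#' \code{snp_id}, harmonizes effect alleles (allele swaps invert the sign;
#' strand flips are complemented), and counts \code{n} = matched signals
#' with reference p below \code{alpha} and \code{k} = those whose effect
#' direction agrees with discovery. \code{(k, n)} feed
#' \code{\link{binomial_consistency_test}}.
#'
#' @param discovery,reference data frames with columns \code{snp_id},
#'   \code{effect_allele}, \code{other_allele}, \code{log_or} (or
#'   \code{beta}), and for \code{reference} also \code{p_value}.
#' @param alpha nominal significance level applied to the reference p.
#' @return List with \code{k}, \code{n}, and \code{excluded} (snp_ids with
#'   irresolvable allele pairs, dropped with a warning).
#' @export
count_consistent_nominal <- function(discovery, reference, alpha = 0.05) {
  check_fraction(alpha, "alpha")
  eff <- function(df) {
    if ("log_or" %in% names(df)) df$log_or else if ("beta" %in% names(df))
      df$beta else stop("need a `log_or` or `beta` column", call. = FALSE)
  }
  d_eff <- eff(discovery)
  r_eff <- eff(reference)
  if (!"p_value" %in% names(reference)) {
    stop("`reference` needs a `p_value` column", call. = FALSE)
  }
  idx <- match(discovery$snp_id, reference$snp_id)
  k <- 0L
  n <- 0L
  excluded <- character(0)
  for (i in which(!is.na(idx))) {
    j <- idx[i]
    sgn <- harmonize_sign(discovery$effect_allele[i],
                          discovery$other_allele[i],
                          reference$effect_allele[j],
                          reference$other_allele[j])
    if (is.na(sgn)) {
      excluded <- c(excluded, discovery$snp_id[i])
      next
    }
    if (reference$p_value[j] < alpha) {
      n <- n + 1L
      if (sign(d_eff[i]) == sign(sgn * r_eff[j])) k <- k + 1L
    }
  }
  if (length(excluded)) {
    warning("excluded records with irresolvable allele pairs: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  list(k = k, n = n, excluded = excluded)
}

# Coerce study input to a data frame with log_or and se_log_or, deriving
# them from or/ci columns where necessary.
as_study_estimates <- function(studies) {
  df <- as.data.frame(studies)
  if (!nrow(df)) stop("no studies supplied", call. = FALSE)
  if (!"log_or" %in% names(df)) {
    if (!"or" %in% names(df)) {
      stop("studies need `log_or` or `or`", call. = FALSE)
    }
    df$log_or <- log(df$or)
  }
  if (!"se_log_or" %in% names(df)) {
    if (!all(c("ci_low", "ci_high") %in% names(df))) {
      stop("studies need `se_log_or` or `ci_low`/`ci_high`", call. = FALSE)
    }
    df$se_log_or <- mapply(se_from_ci, exp(df$log_or), df$ci_low,
                           df$ci_high)
  }
  if (any(!is.finite(df$log_or)) || any(!is.finite(df$se_log_or)) ||
      any(df$se_log_or <= 0)) {
    stop("log ORs must be finite and SEs positive", call. = FALSE)
  }
  df
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-study log odds ratios with weights \eqn{w_s = 1/SE_s^2}:
#' combined \eqn{\hat b = \sum w_s b_s / \sum w_s}, combined
#' \eqn{SE = 1/\sqrt{\sum w_s}}, two-sided normal p, 95% CI on the OR
#' scale. With two or more studies, Cochran's Q heterogeneity statistic is
#' included.
#'
#' @param studies data frame with \code{log_or} and \code{se_log_or}
#'   columns, or \code{or} with \code{ci_low}/\code{ci_high} (SEs are then
#'   back-calculated from the CIs).
#' @return An object of class \code{meta_result}: combined \code{log_or},
#'   \code{se}, \code{or}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{n_studies}, and (for >= 2 studies) \code{q}, \code{q_df},
#'   \code{q_p}.
#' @examples
#' studies <- data.frame(or = c(2.37, 1.54), ci_low = c(1.75, 1.35),
#'                       ci_high = c(3.20, 1.76))
#' fixed_effect_meta(studies)
#' @export
fixed_effect_meta <- function(studies) {
  df <- as_study_estimates(studies)
  w <- 1 / df$se_log_or^2
  b <- sum(w * df$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- if (nrow(df) >= 2L) cochran_q(df) else
    list(q = NA_real_, df = NA_integer_, p_value = NA_real_)
  structure(list(
    log_or = b,
    se = se,
    or = exp(b),
    ci_low = exp(b - Z95 * se),
    ci_high = exp(b + Z95 * se),
    p_value = 2 * pnorm(-abs(b / se)),
    n_studies = nrow(df),
    q = het$q,
    q_df = het$df,
    q_p = het$p_value
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Fixed-effect meta-analysis of %d studies\n  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$n_studies, x$or, x$ci_low, x$ci_high, x$p_value))
  if (!is.na(x$q)) {
    cat(sprintf("  heterogeneity: Q = %.3f (df %d), p = %.3g\n",
                x$q, x$q_df, x$q_p))
  }
  invisible(x)
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_s w_s (b_s - \bar b)^2} with inverse-variance weights and
#' the fixed-effect combined estimate \eqn{\bar b}; chi-square upper tail
#' with S - 1 degrees of freedom.
#'
#' @inheritParams fixed_effect_meta
#' @return List with \code{q}, \code{df}, \code{p_value}.
#' @export
cochran_q <- function(studies) {
  df <- as_study_estimates(studies)
  if (nrow(df) < 2L) stop("Cochran's Q needs at least 2 studies",
                          call. = FALSE)
  w <- 1 / df$se_log_or^2
  b <- sum(w * df$log_or) / sum(w)
  q <- sum(w * (df$log_or - b)^2)
  list(q = q, df = nrow(df) - 1L,
       p_value = pchisq(q, nrow(df) - 1L, lower.tail = FALSE))
}

#' Three-criterion replication decision
#'
#' A discovery signal replicates when it meets all of: (i) direction of
#' effect consistent in every replication cohort; (ii) p < \code{alpha} in
#' at least one replication cohort; (iii) the meta-analysis p reaches
#' genome-wide significance (\code{gw_threshold}, default 5e-8; a stricter
#' 1.17e-8 option accounts for testing denser variant sets).
#'
#' @param discovery one-row data frame (or list) with \code{log_or} (or
#'   \code{or}).
#' @param replications data frame of replication cohorts with \code{log_or}
#'   (or \code{or}) and \code{p_value}.
#' @param meta a \code{\link{fixed_effect_meta}} result for the combined
#'   analysis.
#' @param gw_threshold genome-wide significance threshold.
#' @param alpha per-cohort nominal replication threshold.
#' @return List of class \code{replication_decision} with the three flags,
#'   their conjunction \code{replicated}, and the thresholds used.
#' @export
replication_decision <- function(discovery, replications, meta,
                                 gw_threshold = 5e-8, alpha = 0.05) {
  stopifnot(inherits(meta, "meta_result"))
  check_fraction(alpha, "alpha")
  check_fraction(gw_threshold, "gw_threshold")
  d <- as.data.frame(discovery)
  if (!"log_or" %in% names(d)) d$log_or <- log(d$or)
  r <- as.data.frame(replications)
  if (!"log_or" %in% names(r)) r$log_or <- log(r$or)
  if (!"p_value" %in% names(r)) {
    stop("`replications` needs a `p_value` column", call. = FALSE)
  }
  direction_consistent <- all(sign(r$log_or) == sign(d$log_or[1L])) &&
    d$log_or[1L] != 0
  replication_nominal <- any(r$p_value < alpha)
  meta_genomewide <- meta$p_value < gw_threshold
  structure(list(
    direction_consistent = direction_consistent,
    replication_nominal = replication_nominal,
    meta_genomewide = meta_genomewide,
    replicated = direction_consistent && replication_nominal &&
      meta_genomewide,
    gw_threshold = gw_threshold,
    alpha = alpha
  ), class = "replication_decision")
}

#' @export
print.replication_decision <- function(x, ...) {
  flag <- function(b) if (b) "yes" else "no"
  cat(sprintf(
    paste0("Replication decision (gw threshold %.3g)\n",
           "  direction consistent: %s\n",
           "  p < %.2g in >= 1 replication cohort: %s\n",
           "  meta-analysis genome-wide significant: %s\n",
           "  replicated: %s\n"),
    x$gw_threshold, flag(x$direction_consistent), x$alpha,
    flag(x$replication_nominal), flag(x$meta_genomewide),
    flag(x$replicated)))
  invisible(x)
}
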