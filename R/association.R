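#' Effect-allele frequency from dosages
#'
#' @param dosages numeric vector of effect-allele dosages in [0, 2].
#' @return The allele frequency \code{sum(dosages) / (2 n)}.
#' @examples
#' allele_frequency(c(0, 1, 2))
#' @export
allele_frequency <- function(dosages) {
  d <- as.numeric(dosages)
  if (length(d) == 0L) stop("empty dosage vector", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 2)) {
    stop("dosages must be finite and in [0, 2]", call. = FALSE)
  }
  sum(d) / (2 * length(d))
}

# 1.96, not qnorm(0.975): CI <-> SE conversions must round-trip with
# conventionally reported 95% intervals.
Z95 <- 1.96

#' Allelic odds ratio from a 2x2 allele-count table
#'
#' Woolf's method on the allele-count table: \code{OR = ad / (bc)},
#' \code{SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)}, Wald two-sided normal
#' p-value, and a 95% CI \code{exp(log OR +/- 1.96 SE)}. Group 0 is the
#' reference (lower-BMI) group.
#'
#' @param a,b effect- and other-allele counts in group 1.
#' @param c,d effect- and other-allele counts in group 0 (reference).
#' @param haldane if \code{TRUE}, add 0.5 to every cell when any cell is
#'   zero (Haldane-Anscombe correction); if \code{FALSE} (default) a zero
#'   cell is an error.
#' @return A list of class \code{assoc_or} with \code{or}, \code{log_or},
#'   \code{se_log_or}, \code{ci_low}, \code{ci_high}, \code{p_value}.
#' @examples
#' or_from_counts(30, 70, 20, 80)
#' @export
or_from_counts <- function(a, b, c, d, haldane = FALSE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("allele counts must be finite and non-negative", call. = FALSE)
  }
  if (any(counts == 0)) {
    if (!haldane) {
      stop("zero cell in allele-count table; set haldane = TRUE for a ",
           "continuity correction", call. = FALSE)
    }
    counts <- counts + 0.5
  }
  log_or <- log(counts[["a"]]) + log(counts[["d"]]) -
    log(counts[["b"]]) - log(counts[["c"]])
  se <- sqrt(sum(1 / counts))
  structure(list(
    or = exp(log_or),
    log_or = log_or,
    se_log_or = se,
    ci_low = exp(log_or - Z95 * se),
    ci_high = exp(log_or + Z95 * se),
    p_value = 2 * pnorm(-abs(log_or / se))
  ), class = "assoc_or")
}

#' @export
print.assoc_or <- function(x, ...) {
  cat(sprintf("OR %.4g (95%% CI %.4g-%.4g), p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Allelic odds ratio implied by two allele frequencies
#'
#' \code{(eaf1 / (1 - eaf1)) / (eaf0 / (1 - eaf0))}; group 0 is the
#' reference group.
#'
#' @param eaf1,eaf0 effect-allele frequencies, strictly in (0, 1).
#' @return A single odds ratio.
#' @examples
#' or_from_freqs(2 / 3, 1 / 3)
#' @export
or_from_freqs <- function(eaf1, eaf0) {
  check_fraction(eaf1, "eaf1")
  check_fraction(eaf0, "eaf0")
  (eaf1 / (1 - eaf1)) / (eaf0 / (1 - eaf0))
}

#' Standard error of a log odds ratio from its 95% CI
#'
#' \code{(log(ci_high) - log(ci_low)) / (2 * 1.96)}; the inverse of the
#' conventional CI construction, used to meta-analyse published
#' "OR (95% CI)" columns.
#'
#' @param or_value odds ratio (point estimate).
#' @param ci_low,ci_high 95% CI bounds on the OR scale.
#' @return The SE of the log OR.
#' @examples
#' se_from_ci(1.54, 1.35, 1.76)
#' @export
se_from_ci <- function(or_value, ci_low, ci_high) {
  if (any(!is.finite(c(or_value, ci_low, ci_high))) || ci_low <= 0) {
    stop("OR and CI bounds must be finite and positive", call. = FALSE)
  }
  if (ci_low > or_value || or_value > ci_high) {
    stop("CI must satisfy ci_low <= or_value <= ci_high", call. = FALSE)
  }
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' Nagelkerke's pseudo R-squared
#'
#' \deqn{R^2 = \frac{1 - \exp\{(2/n)(\ell_0 - \ell_1)\}}
#'                  {1 - \exp\{(2/n)\,\ell_0\}}}
#' where \eqn{\ell_0} and \eqn{\ell_1} are the intercept-only and full-model
#' log-likelihoods; the Cox-Snell ratio rescaled to a [0, 1] range.
#'
#' @param loglik_null intercept-only model log-likelihood.
#' @param loglik_full full-model log-likelihood (>= \code{loglik_null}).
#' @param n number of observations.
#' @return R-squared in [0, 1].
#' @examples
#' nagelkerke_r2(-2.7726, -2.0, n = 4)
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  check_number(loglik_null, "loglik_null", upper = 0)
  check_number(loglik_full, "loglik_full", upper = 0)
  check_number(n, "n", lower = 1, integer = TRUE)
  if (loglik_full < loglik_null - 1e-8) {
    stop("loglik_full must be >= loglik_null (nested models)",
         call. = FALSE)
  }
  if (loglik_null == 0) {
    stop("degenerate input: loglik_null = 0 leaves the Nagelkerke ",
         "denominator at zero", call. = FALSE)
  }
  (1 - exp((2 / n) * (loglik_null - loglik_full))) /
    (1 - exp((2 / n) * loglik_null))
}

#' z-test for a difference between two log odds ratios
#'
#' \code{z = (log_or1 - log_or2) / sqrt(se1^2 + se2^2)}, two-sided normal
#' p-value. Used to compare the same variant's effect across control sets
#' (e.g. age-matched vs population controls).
#'
#' @param log_or1,log_or2 log odds ratios.
#' @param se1,se2 their standard errors (> 0).
#' @return A list with \code{z} and \code{p_value}.
#' @examples
#' or_difference_ztest(0.5, 0.1, 0.3, 0.1)
#' @export
or_difference_ztest <- function(log_or1, se1, log_or2, se2) {
  check_number(log_or1, "log_or1")
  check_number(log_or2, "log_or2")
  check_number(se1, "se1", lower = 0, strict = TRUE)
  check_number(se2, "se2", lower = 0, strict = TRUE)
  z <- (log_or1 - log_or2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Observed-scale to liability-scale heritability
#'
#' Converts a case-control (observed-scale) heritability to the liability
#' scale under the threshold model:
#' \deqn{h^2_{liab} = h^2_{obs}\,
#'   \frac{K^2 (1 - K)^2}{z^2\, P (1 - P)}}
#' where \eqn{K} is the population prevalence, \eqn{P} the sample case
#' proportion, and \eqn{z} the standard-normal density at the liability
#' threshold \eqn{\Phi^{-1}(1 - K)}. Relevant prevalences for the extreme
#' BMI cohorts are 0.15% (severe childhood-onset obesity) and 2.8%
#' (persistent thinness, BMI <= 19).
#'
#' @param h2_observed observed-scale heritability, in [0, 1].
#' @param prevalence_k population prevalence, strictly in (0, 1).
#' @param case_proportion_p sample case fraction, strictly in (0, 1).
#' @return Liability-scale heritability.
#' @examples
#' liability_h2(0.2, prevalence_k = 0.0015, case_proportion_p = 0.18)
#' @export
liability_h2 <- function(h2_observed, prevalence_k, case_proportion_p) {
  check_number(h2_observed, "h2_observed", 0, 1)
  check_fraction(prevalence_k, "prevalence_k")
  check_fraction(case_proportion_p, "case_proportion_p")
  K <- prevalence_k
  P <- case_proportion_p
  z <- dnorm(qnorm(1 - K))
  h2_observed * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}
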