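# Weighted standardized genetic risk scores and cumulative-logit ordinal
# regression with proportional, partial, and full non-proportional odds.

#' Weighted standardized genetic risk score
#'
#' Per-individual weighted dosage sum \eqn{\sum_j w_j d_{ij}}, standardized
#' by the sample mean and sample SD (denominator n - 1) over the full
#' analysis set.
#'
#' @param dosages matrix (individuals x loci) of effect-allele dosages, or
#'   a data frame of numeric dosage columns.
#' @param weights per-locus effect sizes; a numeric vector or a
#'   \code{\link{locus_panel}} (its \code{beta} column is used).
#' @return An object of class \code{grs_vector}: list with \code{raw} and
#'   \code{standardized} per-individual scores.
#' @examples
#' compute_grs(matrix(c(0, 1, 2), ncol = 1), weights = 0.1)
#' @export
compute_grs <- function(dosages, weights) {
  if (inherits(weights, "locus_panel")) weights <- weights$beta
  d <- as.matrix(dosages)
  if (!is.numeric(d)) stop("dosages must be numeric", call. = FALSE)
  if (nrow(d) < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (ncol(d) != length(weights)) {
    stop("number of weights must match number of dosage columns",
         call. = FALSE)
  }
  raw <- drop(d %*% as.numeric(weights))
  s <- sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("raw genetic risk scores have zero variance; cannot standardize",
         call. = FALSE)
  }
  structure(list(raw = raw, standardized = (raw - mean(raw)) / s),
            class = "grs_vector")
}

#' @export
print.grs_vector <- function(x, ...) {
  cat(sprintf("Genetic risk score for %d individuals (raw mean %.4g, sd %.4g)\n",
              length(x$raw), mean(x$raw), sd(x$raw)))
  invisible(x)
}

# --- cumulative-logit likelihood machinery ---------------------------------

# Pack/unpack: theta = (alpha_1, log-increments (K-2), shared betas,
# varying betas cutpoint-major). Cutpoint ordering is enforced by the
# first-cutpoint + positive-increments reparameterization.
ordinal_nll <- function(theta, y, X, K, shared_idx, varying_idx) {
  n_cut <- K - 1L
  alpha <- theta[1L]
  if (n_cut > 1L) alpha <- alpha + c(0, cumsum(exp(theta[2:n_cut])))
  pos <- n_cut
  n <- length(y)
  eta <- matrix(0, n, n_cut)
  if (length(shared_idx)) {
    bs <- theta[pos + seq_along(shared_idx)]
    pos <- pos + length(shared_idx)
    eta <- eta + drop(X[, shared_idx, drop = FALSE] %*% bs)
  }
  if (length(varying_idx)) {
    for (k in seq_len(n_cut)) {
      bv <- theta[pos + seq_along(varying_idx)]
      pos <- pos + length(varying_idx)
      eta[, k] <- eta[, k] + drop(X[, varying_idx, drop = FALSE] %*% bv)
    }
  }
  # cumulative P(Y <= k) = plogis(alpha_k - eta_k)
  G <- plogis(sweep(-eta, 2L, alpha, `+`))
  probs <- cbind(G, 1)[, c(1L, seq_len(n_cut) + 1L), drop = FALSE] -
    cbind(0, G)
  p_i <- probs[cbind(seq_len(n), y)]
  if (any(p_i <= 1e-300)) return(1e10)
  -sum(log(p_i))
}

n_ordinal_par <- function(K, n_shared, n_varying) {
  (K - 1L) + n_shared + n_varying * (K - 1L)
}

#' Fit a cumulative-logit ordinal regression
#'
#' Models an ordered BMI category (thin < control < obese) as a function of
#' a genetic risk score and optional covariates through cumulative logits
#' \eqn{\mathrm{logit}\, P(Y \le k) = \alpha_k - \eta_{ik}}. In
#' \code{"proportional"} mode every coefficient is shared across cutpoints
#' (proportional odds); in \code{"partial"} mode the score (and any
#' covariates named in \code{varying_covariates}) get cutpoint-specific
#' coefficients while the rest stay shared; in \code{"full"} mode every
#' coefficient varies. Positive coefficients shift individuals toward the
#' higher (more obese) categories.
#'
#' The likelihood is maximized by BFGS from an intercept-only closed-form
#' start; non-proportional modes warm-start from the proportional solution,
#' which guarantees the nested log-likelihood ordering. Cutpoint ordering
#' is enforced by reparameterization (first cutpoint plus positive
#' increments).
#'
#' @param score numeric predictor or a \code{\link{compute_grs}} result
#'   (its standardized scores are used); \code{NULL} for an intercept-only
#'   fit.
#' @param categories ordered factor (or character coerced with
#'   \code{levels}) of BMI categories, lowest first.
#' @param covariates optional numeric data frame / matrix of covariates
#'   with shared coefficients unless named in \code{varying_covariates}.
#' @param mode \code{"proportional"}, \code{"partial"}, or \code{"full"}.
#' @param varying_covariates covariate names given cutpoint-specific
#'   coefficients in \code{"partial"} mode (the score always varies in
#'   partial mode).
#' @param levels category order used when \code{categories} is not already
#'   an ordered factor.
#' @return An object of class \code{ordinal_fit}: cutpoints, coefficient
#'   table, log-likelihood, parameter count, convergence flag.
#' @examples
#' y <- rep(c("thin", "control", "obese"), times = c(25, 50, 25))
#' fit_ordinal(NULL, y)$cutpoints
#' @export
fit_ordinal <- function(score, categories, covariates = NULL,
                        mode = c("proportional", "partial", "full"),
                        varying_covariates = NULL,
                        levels = c("thin", "control", "obese")) {
  mode <- match.arg(mode)
  if (inherits(score, "grs_vector")) score <- score$standardized
  if (!is.ordered(categories)) {
    present <- if (is.factor(categories)) levels(categories) else
      unique(as.character(categories))
    lv <- if (all(present %in% levels)) levels else sort(present)
    categories <- factor(as.character(categories), levels = lv,
                         ordered = TRUE)
  }
  if (anyNA(categories)) stop("categories contain NA", call. = FALSE)
  categories <- droplevels(categories)
  K <- nlevels(categories)
  if (K < 2L) stop("need at least 2 categories present", call. = FALSE)
  y <- as.integer(categories)
  n <- length(y)

  X <- NULL
  terms <- character(0)
  if (!is.null(score)) {
    if (length(score) != n) stop("score length must match categories",
                                 call. = FALSE)
    X <- cbind(score = as.numeric(score))
    terms <- "score"
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariate rows must match categories",
                            call. = FALSE)
    if (is.null(colnames(cv))) {
      colnames(cv) <- paste0("x", seq_len(ncol(cv)))
    }
    X <- cbind(X, cv)
    terms <- c(terms, colnames(cv))
  }
  if (!is.null(X) && any(!is.finite(X))) {
    stop("predictors must be finite", call. = FALSE)
  }

  varying <- switch(mode,
    proportional = character(0),
    partial = intersect(c(if (!is.null(score)) "score",
                          varying_covariates), terms),
    full = terms)
  shared <- setdiff(terms, varying)
  shared_idx <- match(shared, terms)
  varying_idx <- match(varying, terms)

  # closed-form intercept-only start
  props <- cumsum(tabulate(y, K) / n)[seq_len(K - 1L)]
  alpha0 <- qlogis(props)
  start <- c(alpha0[1L],
             if (K > 2L) log(pmax(diff(alpha0), 1e-3)),
             rep(0, length(shared_idx)),
             rep(0, length(varying_idx) * (K - 1L)))

  if (length(varying_idx) && length(terms)) {
    # warm start from the proportional fit: replicate its shared slope
    # across cutpoints so the free fit can only improve the likelihood
    prop_fit <- fit_ordinal(if (!is.null(score)) score,
                            categories,
                            covariates = covariates,
                            mode = "proportional", levels = levels)
    b_prop <- prop_fit$coefficients$estimate[
      match(terms, prop_fit$coefficients$term)]
    a <- prop_fit$cutpoints
    start <- c(a[1L],
               if (K > 2L) log(pmax(diff(a), 1e-6)),
               b_prop[shared_idx],
               rep(b_prop[varying_idx], times = K - 1L))
  }

  nll <- function(theta) ordinal_nll(theta, y, X, K, shared_idx, varying_idx)
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0L) {
    polish <- optim(opt$par, nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-12))
    if (polish$value <= opt$value) opt <- polish
    opt2 <- optim(opt$par, nll, method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-14))
    if (opt2$value <= opt$value) opt <- opt2
  }
  if (!is.finite(opt$value) || opt$value >= 1e10) {
    stop("ordinal fit failed: likelihood degenerate (possible separation)",
         call. = FALSE)
  }

  theta <- opt$par
  n_cut <- K - 1L
  alpha <- theta[1L]
  if (n_cut > 1L) alpha <- alpha + c(0, cumsum(exp(theta[2:n_cut])))
  names(alpha) <- paste(head(levels(categories), -1L),
                        levels(categories)[-1L], sep = "|")
  pos <- n_cut
  coefs <- NULL
  if (length(shared_idx)) {
    coefs <- data.frame(term = terms[shared_idx], cutpoint = "shared",
                        estimate = theta[pos + seq_along(shared_idx)],
                        stringsAsFactors = FALSE)
    pos <- pos + length(shared_idx)
  }
  if (length(varying_idx)) {
    for (k in seq_len(n_cut)) {
      coefs <- rbind(coefs, data.frame(
        term = terms[varying_idx], cutpoint = names(alpha)[k],
        estimate = theta[pos + seq_along(varying_idx)],
        stringsAsFactors = FALSE))
      pos <- pos + length(varying_idx)
    }
  }

  structure(list(
    cutpoints = alpha,
    coefficients = coefs %||%
      data.frame(term = character(0), cutpoint = character(0),
                 estimate = numeric(0)),
    loglik = -opt$value,
    n = n,
    n_categories = K,
    n_par = n_ordinal_par(K, length(shared_idx), length(varying_idx)),
    mode = mode,
    varying = varying,
    convergence = opt$convergence,
    data_digest = c(n = n, K = K, y_sum = sum(y),
                    x_sum = if (is.null(X)) 0 else round(sum(X), 8))
  ), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Cumulative-logit fit (%s odds), n = %d, logLik = %.4f\n",
              x$mode, x$n, x$loglik))
  cat("cutpoints:\n")
  print(round(x$cutpoints, 4))
  if (nrow(x$coefficients)) {
    co <- x$coefficients
    co$or <- exp(co$estimate)
    print(co, digits = 4)
  }
  invisible(x)
}

#' Per-cutpoint odds ratios of a fitted term
#'
#' Returns \code{exp(coefficient)} for each cutpoint (shared coefficients
#' are replicated). For the score with thin < control < obese categories,
#' the upper cutpoint's OR is the obese vs (thin & control) odds ratio per
#' SD of the score, and the lower cutpoint's OR the (control & obese) vs
#' thin one.
#'
#' @param fit an \code{\link{fit_ordinal}} result.
#' @param term term name (default \code{"score"}).
#' @return Named numeric vector of ORs, one per cutpoint.
#' @export
or_by_cutpoint <- function(fit, term = "score") {
  stopifnot(inherits(fit, "ordinal_fit"))
  co <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (!nrow(co)) stop("term not in fit: ", term, call. = FALSE)
  cuts <- names(fit$cutpoints)
  if (identical(co$cutpoint, "shared")) {
    out <- rep(exp(co$estimate), length(cuts))
  } else {
    out <- exp(co$estimate[match(cuts, co$cutpoint)])
  }
  names(out) <- cuts
  out
}

#' Likelihood-ratio test of the equal-odds (proportional) assumption
#'
#' Compares a proportional-odds fit to a nested fit in which designated
#' coefficients vary by cutpoint: \code{2 * (logLik_free - logLik_equal)}
#' against a chi-square with degrees of freedom equal to the extra
#' parameter count.
#'
#' @param fit_equal the constrained (fewer parameters) fit.
#' @param fit_free the relaxed fit on the same data.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
equal_odds_lrt <- function(fit_equal, fit_free) {
  stopifnot(inherits(fit_equal, "ordinal_fit"),
            inherits(fit_free, "ordinal_fit"))
  if (!isTRUE(all.equal(fit_equal$data_digest, fit_free$data_digest))) {
    stop("fits are not on the same data", call. = FALSE)
  }
  df <- fit_free$n_par - fit_equal$n_par
  if (df <= 0L) stop("`fit_free` must have more parameters than `fit_equal`",
                     call. = FALSE)
  stat <- 2 * (fit_free$loglik - fit_equal$loglik)
  if (stat < -1e-6) {
    stop("free fit has lower likelihood than the constrained fit; ",
         "refit (non-convergence)", call. = FALSE)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Empirical simulation p-value for a GRS test statistic
#'
#' The fraction of simulation replicates whose test statistic is strictly
#' larger than the observed one.
#'
#' @param observed_stat observed test statistic.
#' @param sim_stats numeric vector of simulated statistics (>= 2 draws).
#' @return List with \code{empirical_p}, \code{p_label}, \code{n_sims}.
#' @examples
#' grs_simulation_pvalue(2.5, c(1, 2, 3, 4))
#' @export
grs_simulation_pvalue <- function(observed_stat, sim_stats) {
  check_number(observed_stat, "observed_stat")
  sims <- as.numeric(sim_stats)
  if (length(sims) < 2L) stop("need at least 2 simulated statistics",
                              call. = FALSE)
  if (any(!is.finite(sims))) stop("simulated statistics must be finite",
                                  call. = FALSE)
  k <- sum(sims > observed_stat)
  R <- length(sims)
  list(empirical_p = k / R,
       p_label = if (k == 0L) sprintf("< 1/%d", R) else
         format(k / R, digits = 4),
       n_sims = R)
}

#' Compare an observed mean GRS to its simulated distribution
#'
#' One-sample t-style test of a category's observed mean genetic risk
#' score against the distribution of per-replicate simulated means:
#' statistic \code{(observed - mean(sims)) / sd(sims)}, two-sided p from
#' the t distribution with R - 1 degrees of freedom.
#'
#' @param observed_mean observed mean score in one BMI category.
#' @param sim_means per-replicate simulated means for the same category.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @examples
#' mean_grs_category_test(1.2, c(0.9, 1.0, 1.1))
#' @export
mean_grs_category_test <- function(observed_mean, sim_means) {
  check_number(observed_mean, "observed_mean")
  sims <- as.numeric(sim_means)
  if (length(sims) < 2L) stop("need at least 2 simulated means",
                              call. = FALSE)
  s <- sd(sims)
  if (!is.finite(s) || s == 0) {
    stop("simulated means have zero spread", call. = FALSE)
  }
  stat <- (observed_mean - mean(sims)) / s
  df <- length(sims) - 1L
  list(statistic = stat, df = df,
       p_value = 2 * pt(-abs(stat), df))
}

#' Simulated null distribution of GRS ordinal statistics
#'
#' Runs the additive-model cohort simulator and, for each replicate,
#' computes the genetic risk score of the sampled cohort (weights =
#' panel betas, standardized over the analysis set), fits the
#' proportional-odds and score-varying cumulative-logit models, and
#' records the equal-odds LRT statistic and the mean standardized GRS per
#' BMI category. These draws are the empirical null for
#' \code{\link{grs_simulation_pvalue}} and
#' \code{\link{mean_grs_category_test}}.
#'
#' @param panel a \code{\link{locus_panel}}.
#' @param design a \code{\link{cohort_design}}.
#' @param n_replicates number of replicates.
#' @param seed master seed.
#' @param progress print progress every 50 replicates.
#' @return List with \code{lrt_stats} (length R) and \code{mean_grs}
#'   (R x 3 matrix: thin, control, obese).
#' @export
grs_null_distribution <- function(panel, design,
                                  n_replicates = design$n_replicates,
                                  seed = design$seed, progress = FALSE) {
  panel <- validate_panel(panel)
  reps <- replicate_cohorts(panel, design, function(g, y, assignment, r) {
    lab <- assignment$labels
    assigned <- which(lab != "unassigned")
    grs <- compute_grs(g[assigned, , drop = FALSE], panel$beta)
    cats <- droplevels(lab[assigned])
    fit_eq <- fit_ordinal(grs, cats, mode = "proportional")
    fit_fr <- fit_ordinal(grs, cats, mode = "partial")
    lrt <- equal_odds_lrt(fit_eq, fit_fr)
    list(stat = lrt$statistic,
         means = tapply(grs$standardized, cats, mean)[
           c("thin", "control", "obese")])
  }, n_replicates = n_replicates, seed = seed, progress = progress)
  list(
    lrt_stats = vapply(reps, `[[`, numeric(1), "stat"),
    mean_grs = do.call(rbind, lapply(reps, `[[`, "means"))
  )
}
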