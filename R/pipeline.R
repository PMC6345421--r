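# Pipeline driver: simulate -> deviation test -> GRS analysis -> meta.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    # panel: either a file path (panel_file) or generator settings
    panel_file = NULL,
    n_loci = 97L,
    eaf_low = 0.01,
    eaf_high = 0.99,
    beta_scale = 0.03,
    # cohort design (desk scale by default; set n_individuals = 1e6,
    # n_replicates = 10000 for a full-scale run)
    n_individuals = 1e5,
    n_replicates = 200L,
    truncation_sd = -3,
    upper_tail_fraction = 0.0015,
    lower_tail_fraction = 0.028,
    control_band = c(0.028, 0.75),
    n_cases = 1456L,
    n_thin = 1471L,
    n_controls = 6460L,
    # optional inputs
    observed_case_vs_control = NULL,  # summary-stats file
    observed_control_vs_thin = NULL,
    replication_file = NULL,          # study-estimates file
    # analysis settings
    grs_replicates = 50L,
    alpha = 0.05,
    gw_threshold = 5e-8
  )
}

config_design <- function(config) {
  full <- cohort_design(
    n_replicates = config$n_replicates,
    n_individuals = 1e6,
    truncation_sd = config$truncation_sd,
    upper_tail_fraction = config$upper_tail_fraction,
    lower_tail_fraction = config$lower_tail_fraction,
    control_band = config$control_band,
    n_cases = config$n_cases,
    n_thin = config$n_thin,
    n_controls = config$n_controls,
    seed = config$seed
  )
  if (config$n_individuals != full$n_individuals) {
    full <- scale_design(full, config$n_individuals)
  }
  full
}

config_hash <- function(config) {
  # identifies the analysis settings; output location is not part of them
  config <- config[setdiff(names(config), "out_dir")]
  s <- paste(names(config),
             vapply(config, function(v) paste(format(v), collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  codes <- utf8ToInt(s)
  sprintf("%08x", sum(codes * seq_along(codes)) %% 2147483647)
}

provenance <- function(config, extra = list()) {
  c(list(tool = paste0("bmitails ", packageVersion("bmitails")),
         seed = config$seed,
         config_hash = config_hash(config)),
    extra)
}

read_observed_contrast <- function(path, contrast) {
  ss <- read_summary_stats(path)
  data.frame(snp_id = ss$snp_id, contrast = contrast, or = ss$or,
             stringsAsFactors = FALSE)
}

#' Run the full extreme-sampling analysis pipeline
#'
#' Orchestrates the package's stages from one configuration: generate (or
#' read) a locus panel; run the additive-model odds-ratio ensemble; if
#' observed summary statistics are supplied, compute the per-locus
#' deviation-from-additivity table; run the GRS ordinal analysis on a
#' simulated cohort with a simulation null for the equal-odds statistic;
#' and, if replication study estimates are supplied, run the fixed-effect
#' meta-analysis and replication filter per variant. Every output table
#' carries a provenance header (package version, seed, config hash). A run
#' is fully determined by its configuration, including the seed.
#'
#' @param config named list of settings (missing entries take defaults;
#'   see the configuration section of the package vignette), or the path
#'   to a flat key-value config file readable by \code{\link{read_config}}.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the panel, ensemble, and stage result
#'   tables; files are written under \code{config$out_dir}.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- modifyList(default_run_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))

  for (key in c("observed_case_vs_control", "observed_control_vs_thin",
                "replication_file", "panel_file")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop(sprintf("config `%s` points to a missing file: %s", key,
                   config[[key]]), call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  head0 <- provenance(config)

  # stage: panel
  panel <- if (!is.null(config$panel_file)) {
    read_locus_panel(config$panel_file)
  } else {
    generate_panel(config$n_loci, c(config$eaf_low, config$eaf_high),
                   config$beta_scale, seed = config$seed)
  }
  write_tsv(as.data.frame(panel),
            file.path(config$out_dir, "panel.tsv"), head0)
  design <- config_design(config)
  say("panel: %d loci; design: n = %d, replicates = %d", nrow(panel),
      design$n_individuals, design$n_replicates)

  # stage: additive-model ensemble
  ensemble <- run_ensemble(panel, design, seed = config$seed + 1L)
  ens_summary <- data.frame(
    snp_id = panel$snp_id,
    eaf = panel$eaf,
    beta = panel$beta,
    mean_or_case_vs_control = apply(ensemble$ors[, , 1L, drop = FALSE], 2,
                                    mean),
    mean_or_control_vs_thin = apply(ensemble$ors[, , 2L, drop = FALSE], 2,
                                    mean)
  )
  write_tsv(ens_summary, file.path(config$out_dir, "ensemble_summary.tsv"),
            head0)
  say("ensemble: %d replicates done", design$n_replicates)

  # stage: deviation test against observed summary statistics
  deviation <- NULL
  observed <- rbind(
    if (!is.null(config$observed_case_vs_control)) {
      read_observed_contrast(config$observed_case_vs_control,
                             "case_vs_control")
    },
    if (!is.null(config$observed_control_vs_thin)) {
      read_observed_contrast(config$observed_control_vs_thin,
                             "control_vs_thin")
    }
  )
  if (!is.null(observed) && nrow(observed)) {
    results <- deviation_results(ensemble, observed)
    deviation <- deviation_table(
      results,
      threshold = bonferroni_threshold(nrow(panel), 2L, config$alpha),
      alpha = config$alpha
    )
    write_tsv(deviation, file.path(config$out_dir, "deviation.tsv"),
              c(head0, list(threshold = attr(deviation, "threshold"))))
    say("deviation test: %d nominal, %d after correction",
        sum(deviation$nominal), sum(deviation$corrected))
  }

  # stage: GRS ordinal analysis on one simulated cohort + simulation null
  cohort_seed <- config$seed + 2L
  grs_obs <- with_seed(cohort_seed, {
    g <- simulate_genotypes(panel, design$n_individuals)
    y <- simulate_phenotype(g, panel)
    keep <- truncate_lower_tail(y, design$truncation_sd)
    assignment <- sample_extreme_cohort(y[keep], design)
    assigned <- which(assignment$labels != "unassigned")
    grs <- compute_grs(g[keep, , drop = FALSE][assigned, , drop = FALSE],
                       panel$beta)
    cats <- droplevels(assignment$labels[assigned])
    fit_eq <- fit_ordinal(grs, cats, mode = "proportional")
    fit_fr <- fit_ordinal(grs, cats, mode = "partial")
    lrt <- equal_odds_lrt(fit_eq, fit_fr)
    list(lrt = lrt, fit_eq = fit_eq, fit_fr = fit_fr,
         means = tapply(grs$standardized, cats, mean)[
           c("thin", "control", "obese")])
  })
  null_dist <- grs_null_distribution(panel, design,
                                     n_replicates = config$grs_replicates,
                                     seed = config$seed + 3L)
  sim_p <- grs_simulation_pvalue(grs_obs$lrt$statistic,
                                 null_dist$lrt_stats)
  mean_tests <- lapply(c("thin", "control", "obese"), function(cat) {
    tt <- mean_grs_category_test(grs_obs$means[[cat]],
                                 null_dist$mean_grs[, cat])
    data.frame(category = cat, observed_mean = grs_obs$means[[cat]],
               sim_mean = mean(null_dist$mean_grs[, cat]),
               statistic = tt$statistic, p_value = tt$p_value)
  })
  ors <- or_by_cutpoint(grs_obs$fit_fr)
  grs_table <- data.frame(
    quantity = c("score_or_lower_cutpoint", "score_or_upper_cutpoint",
                 "equal_odds_lrt", "equal_odds_lrt_p",
                 "equal_odds_simulation_p"),
    value = c(ors[[1]], ors[[2]], grs_obs$lrt$statistic,
              grs_obs$lrt$p_value, sim_p$empirical_p)
  )
  write_tsv(grs_table, file.path(config$out_dir, "grs.tsv"), head0)
  write_tsv(do.call(rbind, mean_tests),
            file.path(config$out_dir, "grs_category_means.tsv"), head0)
  say("GRS: equal-odds LRT %.3f (simulation p %s)",
      grs_obs$lrt$statistic, sim_p$p_label)

  # stage: replication meta-analysis
  meta_table <- NULL
  if (!is.null(config$replication_file)) {
    est <- read_study_estimates(config$replication_file)
    rows <- lapply(split(est, est$snp_id), function(snp) {
      disc <- snp[snp$study == "discovery", , drop = FALSE]
      reps <- snp[snp$study != "discovery", , drop = FALSE]
      meta <- fixed_effect_meta(snp)
      decision <- if (nrow(disc) == 1L && nrow(reps) >= 1L) {
        replication_decision(disc, reps, meta,
                             gw_threshold = config$gw_threshold,
                             alpha = config$alpha)
      }
      data.frame(
        snp_id = snp$snp_id[1L],
        n_studies = nrow(snp),
        or = meta$or, ci_low = meta$ci_low, ci_high = meta$ci_high,
        p_value = meta$p_value, q = meta$q, het_p = meta$q_p,
        replicated = if (is.null(decision)) NA else decision$replicated
      )
    })
    meta_table <- do.call(rbind, rows)
    rownames(meta_table) <- NULL
    write_tsv(meta_table, file.path(config$out_dir, "meta.tsv"), head0)
    say("meta-analysis: %d variants", nrow(meta_table))
  }

  invisible(list(config = config, panel = panel, design = design,
                 ensemble = ensemble, deviation = deviation,
                 grs = grs_table, grs_category_means = do.call(rbind, mean_tests),
                 meta = meta_table))
}
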