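#' Construct a locus panel
#'
#' A locus panel holds the per-locus parameterization of the additive
#' polygenic simulator: effect-allele frequency and per-allele effect size in
#' phenotype-SD units, mirroring published GWAS panels of BMI-associated
#' variants (effect allele = BMI-increasing allele).
#'
#' @param snp_id character vector of unique locus labels.
#' @param effect_allele,other_allele single-character alleles; must differ
#'   per locus.
#' @param eaf effect-allele frequencies, strictly in (0, 1).
#' @param beta per-allele additive effects, phenotype-SD units.
#' @return A data frame of class \code{locus_panel} with one row per locus.
#' @examples
#' locus_panel("rs1", "A", "G", eaf = 0.4, beta = 0.08)
#' @export
locus_panel <- function(snp_id, effect_allele, other_allele, eaf, beta) {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = as.character(effect_allele),
    other_allele = as.character(other_allele),
    eaf = as.numeric(eaf),
    beta = as.numeric(beta),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("locus_panel", "data.frame")
  validate_panel(panel)
}

#' Validate a locus panel
#'
#' Checks the panel invariants: unique ids, distinct single-character
#' alleles, frequencies strictly inside (0, 1), finite effect sizes.
#'
#' @param panel a \code{\link{locus_panel}} or compatible data frame.
#' @return The validated panel, invisibly classed as \code{locus_panel}.
#' @export
validate_panel <- function(panel) {
  required <- c("snp_id", "effect_allele", "other_allele", "eaf", "beta")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("locus panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panel) < 1L) stop("locus panel must have at least one locus",
                             call. = FALSE)
  if (anyDuplicated(panel$snp_id)) {
    stop("locus panel snp_ids must be unique", call. = FALSE)
  }
  if (any(panel$effect_allele == panel$other_allele)) {
    stop("effect_allele and other_allele must differ at every locus",
         call. = FALSE)
  }
  if (any(!is.finite(panel$eaf)) || any(panel$eaf <= 0) ||
      any(panel$eaf >= 1)) {
    stop("every eaf must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(panel$beta))) {
    stop("every beta must be finite", call. = FALSE)
  }
  if (!inherits(panel, "locus_panel")) {
    class(panel) <- c("locus_panel", class(panel))
  }
  panel
}

#' Generate a synthetic locus panel
#'
#' Draws a panel of independent biallelic loci emulating an established set
#' of BMI-associated variants: frequencies uniform within \code{eaf_bounds}
#' and positive per-allele effects with magnitudes on the order of
#' \code{beta_scale} SD (log-normal with median \code{beta_scale}, giving
#' the roughly 0.01-0.10 SD range typical of common BMI loci at the
#' default scale).
#'
#' @param n_loci number of loci (>= 1).
#' @param eaf_bounds length-2 numeric, lower < upper, both strictly in
#'   (0, 1).
#' @param beta_scale median per-allele effect magnitude, SD units.
#' @param seed optional integer seed; identical seeds give identical panels.
#' @return A \code{\link{locus_panel}}.
#' @examples
#' panel <- generate_panel(97, seed = 1)
#' range(panel$eaf)
#' @export
generate_panel <- function(n_loci, eaf_bounds = c(0.01, 0.99),
                           beta_scale = 0.03, seed = NULL) {
  check_number(n_loci, "n_loci", lower = 1, integer = TRUE)
  if (length(eaf_bounds) != 2L || !is.numeric(eaf_bounds) ||
      any(!is.finite(eaf_bounds)) ||
      eaf_bounds[1] <= 0 || eaf_bounds[2] >= 1 ||
      eaf_bounds[1] >= eaf_bounds[2]) {
    stop("`eaf_bounds` must satisfy 0 < lower < upper < 1", call. = FALSE)
  }
  check_number(beta_scale, "beta_scale", lower = 0, strict = TRUE)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    eaf <- runif(n_loci, eaf_bounds[1], eaf_bounds[2])
    beta <- beta_scale * exp(rnorm(n_loci, 0, 0.5))
    ea <- sample(bases, n_loci, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))
    locus_panel(
      snp_id = sprintf("snp%0*d", max(3L, nchar(n_loci)), seq_len(n_loci)),
      effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta
    )
  })
}

#' Additive genetic variance of a panel
#'
#' Sum over loci of \eqn{2 p (1 - p) \beta^2}, the phenotypic variance
#' explained by the panel under Hardy-Weinberg and linkage equilibrium.
#'
#' @param panel a \code{\link{locus_panel}}.
#' @return A single non-negative number.
#' @export
genetic_variance <- function(panel) {
  panel <- validate_panel(panel)
  sum(2 * panel$eaf * (1 - panel$eaf) * panel$beta^2)
}

#' Read / write a locus panel file
#'
#' Tab-separated text with header
#' \code{snp_id effect_allele other_allele eaf beta}, one row per locus.
#' Lines starting with \code{#} are treated as comments.
#'
#' @param path file path.
#' @return \code{read_locus_panel} returns a \code{\link{locus_panel}};
#'   \code{write_locus_panel} returns \code{path} invisibly.
#' @export
read_locus_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_panel(raw)
}

#' @rdname read_locus_panel
#' @param panel a \code{\link{locus_panel}}.
#' @export
write_locus_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  write_tsv(as.data.frame(panel), path)
  invisible(path)
}

#' @export
print.locus_panel <- function(x, ...) {
  cat(sprintf("Locus panel: %d loci, genetic variance %.4f\n", nrow(x),
              genetic_variance(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more loci\n", nrow(x) - 6L))
  invisible(x)
}
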