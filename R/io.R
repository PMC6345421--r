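# File formats: tab-separated summary statistics, study estimate tables,
# flat key-value configuration, and provenance-stamped output tables.

#' Parse numbers in published scientific-notation dialects
#'
#' Accepts both machine notation (\code{1.15E-15}) and typeset notation
#' (\code{1.15x10^-15}).
#'
#' @param x character (or numeric) vector.
#' @return Numeric vector; unparseable entries become NA with a warning.
#' @examples
#' parse_scientific(c("1.15E-15", "1.15x10^-15", "0.003"))
#' @export
parse_scientific <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  cleaned <- gsub("\\s", "", as.character(x))
  cleaned <- gsub("[xX]10\\^?", "e", cleaned)
  out <- suppressWarnings(as.numeric(cleaned))
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    warning("unparseable numeric value(s): ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Parse a combined "OR(95%CI)" cell
#'
#' Published tables often print the odds ratio and its confidence interval
#' in one cell, \code{"X(Y,Z)"} (e.g. \code{"1.65(1.46,1.87)"}). Returns
#' the three numbers.
#'
#' @param x character vector of combined cells.
#' @return Data frame with columns \code{or}, \code{ci_low},
#'   \code{ci_high}.
#' @examples
#' parse_or_ci("1.65(1.46,1.87)")
#' @export
parse_or_ci <- function(x) {
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*\\(\\s*([0-9.eE+-]+)\\s*,\\s*([0-9.eE+-]+)\\s*\\)\\s*$",
                             as.character(x)))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("cannot parse OR(CI) cell(s): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(m, function(g) as.numeric(g[2:4])))
  data.frame(or = out[, 1], ci_low = out[, 2], ci_high = out[, 3])
}

# write a data frame as TSV, optionally preceded by '# key: value'
# provenance comment lines
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) {
    writeLines(sprintf("# %s: %s", names(header),
                       vapply(header, format, character(1))), con)
  }
  write.table(format(df, digits = 12, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-locus summary-statistics file
#'
#' Tab-separated text with header columns \code{snp_id},
#' \code{effect_allele}, \code{other_allele}, \code{or}, \code{ci_low},
#' \code{ci_high}, \code{p} (optionally \code{chr}, \code{pos},
#' \code{eaf_group1}, \code{eaf_group0}). A combined \code{or_ci} column in
#' the \code{"X(Y,Z)"} dialect is accepted in place of the three OR
#' columns, and p-values may use either scientific-notation dialect.
#' Lines starting with \code{#} are comments. Each record is validated
#' (positive OR, ordered CI containing the OR, p in (0, 1]); offending
#' rows are reported by number.
#'
#' @param path file path.
#' @return Data frame of class \code{summary_stats} with derived
#'   \code{log_or} and \code{se_log_or} columns.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  if ("or_ci" %in% names(df) && !"or" %in% names(df)) {
    df <- cbind(df, parse_or_ci(df$or_ci))
  } else {
    for (col in intersect(c("or", "ci_low", "ci_high"), names(df))) {
      df[[col]] <- parse_scientific(df[[col]])
    }
  }
  required <- c("snp_id", "effect_allele", "other_allele", "or", "ci_low",
                "ci_high", "p")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("summary-statistics file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$p_value <- parse_scientific(df$p)
  for (col in intersect(c("eaf_group1", "eaf_group0", "pos"), names(df))) {
    df[[col]] <- parse_scientific(df[[col]])
  }

  bad <- which(!is.finite(df$or) | df$or <= 0 |
                 !is.finite(df$ci_low) | df$ci_low <= 0 |
                 !is.finite(df$ci_high) |
                 df$ci_low > df$or | df$or > df$ci_high |
                 !is.finite(df$p_value) | df$p_value <= 0 | df$p_value > 1)
  if (length(bad)) {
    stop("invalid summary-statistics record(s) at data row(s): ",
         paste(bad, collapse = ", "),
         " (need 0 < ci_low <= or <= ci_high and p in (0, 1])",
         call. = FALSE)
  }
  df$log_or <- log(df$or)
  df$se_log_or <- mapply(se_from_ci, df$or, df$ci_low, df$ci_high)
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Read a multi-study estimate table for meta-analysis
#'
#' Tab-separated text with columns \code{snp_id}, \code{study},
#' \code{effect_allele}, \code{other_allele}, \code{or}, \code{ci_low},
#' \code{ci_high}, \code{p}; one row per (variant, study).
#'
#' @param path file path.
#' @return Data frame with derived \code{log_or}, \code{se_log_or},
#'   \code{p_value}.
#' @export
read_study_estimates <- function(path) {
  if (!file.exists(path)) {
    stop("study-estimates file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  required <- c("snp_id", "study", "or", "ci_low", "ci_high")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("study-estimates file missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("p" %in% names(df)) df$p_value <- parse_scientific(df$p)
  df$log_or <- log(df$or)
  df$se_log_or <- mapply(se_from_ci, df$or, df$ci_low, df$ci_high)
  df
}

#' Read / write a flat key-value configuration file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment.
#' Values that parse as numbers become numeric; comma-separated values
#' become vectors (so \code{control_band = 0.028, 0.75} round-trips).
#'
#' @param path file path.
#' @return \code{read_config} returns a named list; \code{write_config}
#'   returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (no '='): ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), length(names(config)) == length(config))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k,
            paste(format(config[[k]], digits = 12), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
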