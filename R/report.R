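#' Render an "OR (95% CI)" string
#'
#' Odds ratio and interval bounds rounded to 3 decimals with trailing zeros
#' trimmed ("0.99", not "0.990"), joined with an en dash.
#'
#' @param beta log-OR effect.
#' @param se standard error.
#' @param level confidence level.
#' @return character, e.g. `"0.994 (0.99–0.999)"`.
#' @export
#' @examples
#' render_or_ci(-0.00572, 0.00227)
render_or_ci <- function(beta, se, level = 0.95) {
  or <- beta_to_or(beta, se, level)
  fmt <- function(x) {
    vapply(round(x, 3), function(v) {
      format(v, drop0trailing = TRUE, scientific = FALSE, trim = TRUE)
    }, character(1))
  }
  sprintf("%s (%s–%s)", fmt(or$or_point), fmt(or$ci_low),
          fmt(or$ci_high))
}

# Fixed report rounding: beta/se/p to 5 decimals.
.fmt5 <- function(x) formatC(x, digits = 5, format = "f")

#' Forest-style estimates table
#'
#' One row per exposure and method (IVW and MR-Egger), with columns Outcome,
#' Exposure, Method, nSNPs, Beta, SE, P-value, OR (95% CI). Beta/SE/p are
#' printed to 5 decimals, OR and CI to 3. An empty input yields an empty
#' table.
#'
#' @param calls a `causal_calls` data frame (see [run_discovery()]).
#' @return data frame of formatted character columns.
#' @export
format_forest_table <- function(calls) {
  cols <- c("Outcome", "Exposure", "Method", "nSNPs", "Beta", "SE",
            "P-value", "OR (95% CI)")
  empty <- as.data.frame(matrix(character(0), ncol = length(cols),
                                dimnames = list(NULL, cols)),
                         check.names = FALSE)
  if (nrow(calls) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$ivw_beta[i])) next
    rows[[length(rows) + 1]] <- data.frame(
      Outcome = calls$outcome_id[i], Exposure = calls$exposure_id[i],
      Method = "MR-Egger", nSNPs = calls$nsnp[i],
      Beta = .fmt5(calls$egger_beta[i]), SE = .fmt5(calls$egger_se[i]),
      `P-value` = .fmt5(calls$egger_p[i]),
      `OR (95% CI)` = render_or_ci(calls$egger_beta[i], calls$egger_se[i]),
      check.names = FALSE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      Outcome = calls$outcome_id[i], Exposure = calls$exposure_id[i],
      Method = "IVW", nSNPs = calls$nsnp[i],
      Beta = .fmt5(calls$ivw_beta[i]), SE = .fmt5(calls$ivw_se[i]),
      `P-value` = .fmt5(calls$ivw_p[i]),
      `OR (95% CI)` = render_or_ci(calls$ivw_beta[i], calls$ivw_se[i]),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Pleiotropy/heterogeneity table
#'
#' One row per fitted exposure with the Egger intercept test and Cochran Q,
#' rounded to 4 decimals.
#'
#' @param calls a `causal_calls` data frame.
#' @return data frame with columns Outcome, Exposure, Egger intercept, SE,
#'   P-value, Q, Q_df, Q_Pval.
#' @export
format_sensitivity_table <- function(calls) {
  fitted <- calls[!is.na(calls$ivw_beta), , drop = FALSE]
  details <- attr(calls, "details")
  f4 <- function(x) formatC(x, digits = 4, format = "f")
  se <- vapply(fitted$exposure_id, function(id) {
    d <- details[[id]]
    if (!is.null(d) && isTRUE(d$fitted)) d$sens$egger_intercept_se else NA_real_
  }, numeric(1))
  data.frame(
    Outcome = fitted$outcome_id, Exposure = fitted$exposure_id,
    `Egger intercept` = f4(fitted$egger_intercept), SE = f4(se),
    `P-value` = f4(fitted$egger_intercept_p), Q = f4(fitted$q_stat),
    Q_df = fitted$q_df, Q_Pval = f4(fitted$q_pvalue),
    check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

#' Long-format leave-one-out table across exposures
#'
#' @param calls a `causal_calls` data frame with fit details attached.
#' @return data frame: `outcome_id`, `exposure_id`, `left_out`, `nsnp`,
#'   `beta`, `se`, `pvalue`.
#' @export
format_loo_table <- function(calls) {
  details <- attr(calls, "details")
  rows <- list()
  for (id in names(details)) {
    d <- details[[id]]
    if (is.null(d) || !isTRUE(d$fitted)) next
    loo <- d$sens$loo
    rows[[length(rows) + 1]] <- data.frame(
      outcome_id = calls$outcome_id[match(id, calls$exposure_id)],
      exposure_id = id, left_out = loo$rsid, nsnp = loo$nsnp,
      beta = loo$beta, se = loo$se, pvalue = loo$pvalue,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(outcome_id = character(0), exposure_id = character(0),
                      left_out = character(0), nsnp = integer(0),
                      beta = numeric(0), se = numeric(0),
                      pvalue = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Parse an "OR (95% CI)" string back to numbers
#'
#' Inverse of [render_or_ci()] at the declared 3-decimal precision.
#'
#' @param s character vector like `"0.994 (0.99–0.999)"`.
#' @return data frame `or_point`, `ci_low`, `ci_high`.
#' @export
parse_or_ci <- function(s) {
  m <- regmatches(s, regexec("^([0-9.]+) \\(([0-9.]+)–([0-9.]+)\\)$", s))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("unparseable OR (95% CI) string: ", s[bad][1])
  out <- do.call(rbind, lapply(m, function(g) as.numeric(g[2:4])))
  data.frame(or_point = out[, 1], ci_low = out[, 2], ci_high = out[, 3])
}

#' Write a run manifest
#'
#' Records the configuration snapshot, input-file MD5 digests, package
#' version, timestamp and per-stage record counts next to a run's outputs so
#' any result table can be traced to its inputs and thresholds.
#'
#' @param dir output directory.
#' @param config configuration list.
#' @param inputs character vector of input file paths.
#' @param counts named numeric vector of per-stage record counts.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, config, inputs = character(0),
                               counts = numeric(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "manifest.txt")
  lines <- c(
    paste0("package: mirmr ", as.character(utils::packageVersion("mirmr"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "config:",
    paste0("  ", names(config), ": ",
           vapply(config, function(x) paste(x, collapse = ","), character(1)))
  )
  if (length(inputs) > 0) {
    digests <- tools::md5sum(inputs)
    lines <- c(lines, "inputs:",
               paste0("  ", names(digests), ": ", digests))
  }
  if (length(counts) > 0) {
    lines <- c(lines, "counts:",
               paste0("  ", names(counts), ": ", counts))
  }
  writeLines(lines, path)
  invisible(path)
}
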