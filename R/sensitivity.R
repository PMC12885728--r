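#' Cochran Q heterogeneity statistic
#'
#' `Q = sum_j (Gamma_j - beta * gamma_j)^2 / se_Gamma_j^2` about the
#' fixed-effect IVW estimate, chi-square distributed with J - 1 degrees of
#' freedom under homogeneity. A small p-value indicates that the per-SNP Wald
#' ratios disagree more than their sampling errors allow.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @param beta_ivw the pooled estimate to measure dispersion about; defaults
#'   to the fixed-effect IVW estimate of `h`.
#' @return list with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(h, beta_ivw = NULL) {
  stopifnot(inherits(h, "harmonized_set"))
  s <- h$snps
  J <- nrow(s)
  if (J < 2) stop("insufficient instruments for Cochran Q (", J, " < 2)")
  if (is.null(beta_ivw)) beta_ivw <- mr_ivw(h, mode = "fixed")$beta
  q <- sum((s$Gamma - beta_ivw * s$gamma)^2 / s$se_Gamma^2)
  df <- J - 1L
  list(q_stat = q, q_df = df, q_pvalue = heterogeneity_pvalue(q, df))
}

#' Upper-tail chi-square p-value for a heterogeneity statistic
#'
#' @param q non-negative statistic.
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
#' @examples
#' heterogeneity_pvalue(33.8242, 39)
heterogeneity_pvalue <- function(q, df) {
  if (any(q < 0)) stop("q must be non-negative")
  stats::pchisq(q, df = df, lower.tail = FALSE)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept component of [mr_egger()]: an average pleiotropic
#' effect significantly different from zero (two-sided t, J - 2 df) indicates
#' directional horizontal pleiotropy biasing the IVW estimate.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(h) {
  it <- mr_egger(h)$intercept
  list(intercept = it$beta, se = it$se, pvalue = it$pvalue)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator excluding each SNP in turn, in the harmonized
#' set's SNP order. A reduced fit that moves far from the full estimate flags
#' a single dominant (possibly pleiotropic) variant.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param mode IVW mode passed to [mr_ivw()].
#' @return data frame with one row per left-out SNP: `rsid`, `nsnp`, `beta`,
#'   `se`, `pvalue`, `or_point`, `ci_low`, `ci_high`.
#' @export
leave_one_out <- function(h, mode = c("mre", "fixed")) {
  stopifnot(inherits(h, "harmonized_set"))
  mode <- match.arg(mode)
  J <- nrow(h$snps)
  if (J < 3) stop("insufficient instruments for leave-one-out (", J, " < 3)")
  rows <- lapply(seq_len(J), function(j) {
    e <- mr_ivw(subset_harmonized(h, -j), mode = mode)
    data.frame(rsid = h$snps$rsid[j], nsnp = e$nsnp, beta = e$beta, se = e$se,
               pvalue = e$pvalue, or_point = e$or_point, ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran Q heterogeneity (about the fixed-effect IVW estimate), the
#' MR-Egger intercept test and the leave-one-out series.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param mode IVW mode for the leave-one-out refits.
#' @return an object of class `sensitivity_report`: list with `exposure_id`,
#'   `outcome_id`, `q_stat`, `q_df`, `q_pvalue`, `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pvalue`, `loo`.
#' @export
sensitivity_report <- function(h, mode = c("mre", "fixed")) {
  mode <- match.arg(mode)
  q <- cochran_q(h)
  it <- egger_intercept_test(h)
  structure(list(exposure_id = h$exposure_id, outcome_id = h$outcome_id,
                 q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
                 egger_intercept = it$intercept, egger_intercept_se = it$se,
                 egger_intercept_pvalue = it$pvalue,
                 loo = leave_one_out(h, mode = mode)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity for %s on %s\n", x$exposure_id, x$outcome_id))
  cat(sprintf("  Cochran Q = %.4f (df %d), p = %.4f\n", x$q_stat, x$q_df,
              x$q_pvalue))
  cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.4f\n",
              x$egger_intercept, x$egger_intercept_se,
              x$egger_intercept_pvalue))
  cat(sprintf("  leave-one-out: %d refits, beta range [%.5f, %.5f]\n",
              nrow(x$loo), min(x$loo$beta), max(x$loo$beta)))
  invisible(x)
}
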