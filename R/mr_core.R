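#' Odds ratio and confidence interval from a log-odds effect
#'
#' `OR = exp(beta)`, with a Wald interval `exp(beta -/+ z * se)` at the normal
#' quantile `z = qnorm((1 + level) / 2)`.
#'
#' @param beta log-OR scale effect.
#' @param se standard error, > 0.
#' @param level confidence level (default 0.95).
#' @return list with `or_point`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' beta_to_or(-0.00572, 0.00227) # OR 0.994, CI 0.990-0.999
beta_to_or <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) stop("se must be > 0")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  list(or_point = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

#' Two-sided p-value for an estimate
#'
#' Normal reference by default; Student t with `df` degrees of freedom when
#' `df` is given (used for MR-Egger coefficients).
#'
#' @param beta estimate.
#' @param se standard error, > 0.
#' @param df optional t degrees of freedom.
#' @return two-sided p-value.
#' @export
mr_pvalue <- function(beta, se, df = NULL) {
  if (any(se <= 0)) stop("se must be > 0")
  z <- abs(beta / se)
  if (is.null(df)) 2 * stats::pnorm(-z) else 2 * stats::pt(-z, df = df)
}

# Construct one causal estimate row.
new_mr_estimate <- function(exposure_id, outcome_id, method, nsnp, beta, se,
                            pvalue, ci_level = 0.95) {
  or <- beta_to_or(beta, se, ci_level)
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 method = method, nsnp = nsnp, beta = beta, se = se,
                 pvalue = pvalue, or_point = or$or_point, ci_low = or$ci_low,
                 ci_high = or$ci_high, ci_level = ci_level),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: %s on %s | nSNP=%d beta=%.5f se=%.5f p=%.5f OR=%s\n",
              x$method, x$exposure_id, x$outcome_id, x$nsnp, x$beta, x$se,
              x$pvalue, render_or_ci(x$beta, x$se, x$ci_level)))
  invisible(x)
}

#' Per-SNP Wald ratio estimates
#'
#' `beta_j = Gamma_j / gamma_j` with first-order standard error
#' `se_j = se_Gamma_j / |gamma_j|`.
#'
#' @param h a `harmonized_set`.
#' @return data frame `rsid`, `beta`, `se`.
#' @export
wald_ratios <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  s <- h$snps
  if (any(s$gamma == 0)) {
    stop("degenerate instrument (gamma = 0): ",
         paste(s$rsid[s$gamma == 0], collapse = ", "))
  }
  data.frame(rsid = s$rsid, beta = s$Gamma / s$gamma,
             se = s$se_Gamma / abs(s$gamma), stringsAsFactors = FALSE)
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted regression of the outcome effects on the exposure effects through
#' the origin, with weights `1 / se_Gamma^2`:
#' `beta = sum(w * gamma * Gamma) / sum(w * gamma^2)`. In `"fixed"` mode the
#' standard error is `sqrt(1 / sum(w * gamma^2))`; in the default `"mre"`
#' (multiplicative random effects) mode it is inflated by the residual scale
#' `sqrt(Q / (J - 1))`, floored at 1, so that between-SNP heterogeneity widens
#' the interval but can never shrink it. P-values use the normal reference.
#' With a single SNP, fixed mode reduces to the Wald ratio.
#'
#' @param h a `harmonized_set`.
#' @param mode `"mre"` (default) or `"fixed"`.
#' @param ci_level confidence level for the OR interval.
#' @return an `mr_estimate` with method `"ivw_mre"` or `"ivw_fe"`.
#' @export
mr_ivw <- function(h, mode = c("mre", "fixed"), ci_level = 0.95) {
  stopifnot(inherits(h, "harmonized_set"))
  mode <- match.arg(mode)
  s <- h$snps
  J <- nrow(s)
  min_j <- if (mode == "fixed") 1L else 2L
  if (J < min_j) {
    stop("insufficient instruments for IVW (", J, " < ", min_j, ") for ",
         h$exposure_id)
  }
  w <- 1 / s$se_Gamma^2
  denom <- sum(w * s$gamma^2)
  beta <- sum(w * s$gamma * s$Gamma) / denom
  se_fixed <- sqrt(1 / denom)
  if (mode == "mre") {
    Q <- sum(w * (s$Gamma - beta * s$gamma)^2)
    phi <- sqrt(Q / (J - 1))
    se <- se_fixed * max(1, phi)
  } else {
    se <- se_fixed
  }
  new_mr_estimate(h$exposure_id, h$outcome_id,
                  if (mode == "mre") "ivw_mre" else "ivw_fe",
                  J, beta, se, mr_pvalue(beta, se), ci_level)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' an unconstrained intercept, weights `1 / se_Gamma^2`, fitted after
#' orienting all exposure effects non-negative (jointly flipping the sign of
#' each (gamma_j, Gamma_j) pair with gamma_j < 0 — without this the intercept
#' is not identifiable under allele recoding). The intercept estimates the
#' average directional pleiotropic effect; the slope is a pleiotropy-robust
#' causal estimate under the InSIDE assumption. Standard errors are the
#' unscaled WLS errors multiplied by the residual scale floored at 1;
#' p-values use the t distribution with J - 2 degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param ci_level confidence level for the OR interval.
#' @return list with `slope` and `intercept`, both `mr_estimate`s.
#' @export
mr_egger <- function(h, ci_level = 0.95) {
  stopifnot(inherits(h, "harmonized_set"))
  s <- h$snps
  J <- nrow(s)
  if (J < 3) {
    stop("insufficient instruments for MR-Egger (", J, " < 3) for ",
         h$exposure_id)
  }
  flip <- sign(s$gamma)
  flip[flip == 0] <- 1
  g <- s$gamma * flip
  G <- s$Gamma * flip
  w <- 1 / s$se_Gamma^2

  fit <- stats::lm(G ~ g, weights = w)
  est <- stats::coef(fit)
  # unscaled (X' W X)^{-1} standard errors, then multiplicative scale >= 1
  xtwx_inv <- summary(fit)$cov.unscaled
  sigma <- summary(fit)$sigma
  se_unscaled <- sqrt(diag(xtwx_inv))
  se <- se_unscaled * max(1, sigma)

  slope <- new_mr_estimate(h$exposure_id, h$outcome_id, "egger_slope", J,
                           est[["g"]], se[["g"]],
                           mr_pvalue(est[["g"]], se[["g"]], df = J - 2),
                           ci_level)
  intercept <- new_mr_estimate(h$exposure_id, h$outcome_id, "egger_intercept",
                               J, est[["(Intercept)"]], se[["(Intercept)"]],
                               mr_pvalue(est[["(Intercept)"]],
                                         se[["(Intercept)"]], df = J - 2),
                               ci_level)
  list(slope = slope, intercept = intercept)
}
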