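#' Default pipeline configuration
#'
#' Thresholds for instrument selection, harmonization and the causal-call
#' criteria. Defaults: instrument FDR < 0.1, F > 10, clumping at r^2 < 0.5 in
#' a 10-kb window, outcome-significant exclusion at p <= 5e-8, causal call at
#' IVW p < .05 and cross-exposure FDR < 0.1 with direction agreement between
#' IVW and MR-Egger and at least 3 SNPs, validation instruments at p < 1e-5,
#' replication requiring IVW p < .05 with the discovery direction.
#'
#' @param ... named overrides.
#' @return named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(
    fdr_instrument = 0.1,
    f_min = 10,
    r2_clump = 0.5,
    window_bp = 10000,
    p_outcome_exclude = 5e-8,
    p_causal = 0.05,
    fdr_decision = 0.1,
    min_nsnp = 3L,
    p_validation_instrument = 1e-5,
    require_direction_replication = TRUE,
    ivw_mode = "mre",
    ci_level = 0.95
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0) stop("unknown config setting(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

# Fit one exposure against one outcome: harmonize, exclude outcome-significant
# SNPs, and (when enough SNPs survive) fit IVW + Egger + sensitivity.
.fit_pair <- function(records, outcome, config) {
  h <- suppressWarnings(harmonize(records, outcome))
  h <- suppressWarnings(
    filter_outcome_significant(h, threshold = config$p_outcome_exclude))
  J <- nrow(h$snps)
  if (J < config$min_nsnp) {
    return(list(h = h, nsnp = J, fitted = FALSE))
  }
  ivw <- mr_ivw(h, mode = config$ivw_mode, ci_level = config$ci_level)
  egger <- mr_egger(h, ci_level = config$ci_level)
  sens <- sensitivity_report(h, mode = config$ivw_mode)
  list(h = h, nsnp = J, fitted = TRUE, ivw = ivw, egger = egger, sens = sens)
}

#' Discovery-phase causal screening across exposures
#'
#' For each exposure: harmonize against the outcome, drop outcome
#' genome-wide-significant SNPs, and fit IVW, MR-Egger and the sensitivity
#' battery. Benjamini-Hochberg FDR is then applied across the IVW p-values of
#' all exposures actually fitted for this outcome (that set is the FDR
#' family). Each exposure is scored against four criteria: IVW p < .05,
#' cross-exposure FDR q < 0.1, sign agreement between the IVW and Egger slope
#' estimates, and at least 3 SNPs in the fit; `discovery_pass` is their
#' conjunction. Exposures failing the SNP-count gate are reported with
#' `discovery_pass = FALSE` and estimate columns `NA`.
#'
#' @param exposures named list of instrument-ready exposure record data frames
#'   (or `summary_stats` / `instrument_set` objects), one per exposure.
#' @param outcome outcome records (`summary_stats` object or data frame).
#' @param outcome_id outcome identifier used in the output (default: the
#'   `summary_stats` id, else `"outcome"`).
#' @param config see [default_config()].
#' @return an object of class `causal_calls`: a data frame with one row per
#'   exposure (estimates, diagnostics, criterion flags, `discovery_pass`,
#'   `replication_pass` = `NA`, `high_confidence` = `FALSE`), with the full
#'   per-exposure fit objects in `attr(, "details")`.
#' @export
run_discovery <- function(exposures, outcome, outcome_id = NULL,
                          config = default_config()) {
  if (length(exposures) == 0) stop("empty exposure map")
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    stop("exposures must be a named list (exposure_id -> records)")
  }
  if (is.null(outcome_id)) {
    outcome_id <- if (inherits(outcome, "summary_stats")) outcome$id else "outcome"
  }
  exposures <- lapply(exposures, function(x) {
    if (inherits(x, "instrument_set")) x$records else x
  })

  fits <- lapply(names(exposures), function(id) {
    rec <- .records_of(exposures[[id]], id)$records
    .fit_pair(structure(list(role = "exposure", id = id, records = rec,
                             rejects = NULL), class = "summary_stats"),
              outcome, config)
  })
  names(fits) <- names(exposures)

  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    if (!f$fitted) {
      return(data.frame(
        exposure_id = id, outcome_id = outcome_id, nsnp = f$nsnp,
        ivw_beta = NA_real_, ivw_se = NA_real_, ivw_p = NA_real_,
        ivw_q = NA_real_, or_point = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, egger_beta = NA_real_, egger_se = NA_real_,
        egger_p = NA_real_, egger_intercept = NA_real_,
        egger_intercept_p = NA_real_, q_stat = NA_real_, q_df = NA_integer_,
        q_pvalue = NA_real_, pass_pvalue = FALSE, pass_fdr = FALSE,
        pass_direction = FALSE, pass_nsnp = FALSE,
        stringsAsFactors = FALSE))
    }
    data.frame(
      exposure_id = id, outcome_id = outcome_id, nsnp = f$nsnp,
      ivw_beta = f$ivw$beta, ivw_se = f$ivw$se, ivw_p = f$ivw$pvalue,
      ivw_q = NA_real_, or_point = f$ivw$or_point, ci_low = f$ivw$ci_low,
      ci_high = f$ivw$ci_high, egger_beta = f$egger$slope$beta,
      egger_se = f$egger$slope$se, egger_p = f$egger$slope$pvalue,
      egger_intercept = f$egger$intercept$beta,
      egger_intercept_p = f$egger$intercept$pvalue,
      q_stat = f$sens$q_stat, q_df = f$sens$q_df, q_pvalue = f$sens$q_pvalue,
      pass_pvalue = f$ivw$pvalue < config$p_causal,
      pass_fdr = FALSE,
      pass_direction = sign(f$ivw$beta) == sign(f$egger$slope$beta) &
        sign(f$ivw$beta) != 0,
      pass_nsnp = f$nsnp >= config$min_nsnp,
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)

  fitted <- !is.na(calls$ivw_p)
  if (any(fitted)) {
    calls$ivw_q[fitted] <- bh_fdr(calls$ivw_p[fitted])
    calls$pass_fdr <- !is.na(calls$ivw_q) & calls$ivw_q < config$fdr_decision
  }
  calls$discovery_pass <- calls$pass_pvalue & calls$pass_fdr &
    calls$pass_direction & calls$pass_nsnp
  calls$replication_pass <- NA
  calls$high_confidence <- FALSE
  rownames(calls) <- NULL
  structure(calls, class = c("causal_calls", "data.frame"), details = fits,
            config = config)
}

#' Replicate discovery calls in an independent exposure cohort
#'
#' For each discovery-passing call whose exposure is present in the validation
#' map, re-harmonizes the validation instruments against the outcome and
#' refits IVW. `replication_pass` is `TRUE` when the validation IVW p-value is
#' below `config$p_causal` and (by default) the validation estimate has the
#' discovery sign; `FALSE` when the refit is non-significant, wrong-signed, or
#' impossible (too few overlapping SNPs); `NA` ("unavailable") when the
#' exposure is absent from the validation cohort. `high_confidence` is set for
#' calls that pass discovery and replication.
#'
#' @param calls a `causal_calls` object from [run_discovery()].
#' @param validation_exposures named list of validation exposure records.
#' @param outcome outcome records (same outcome dataset as discovery).
#' @param config see [default_config()].
#' @return the `causal_calls` with `replication_pass`, `high_confidence` and
#'   `repl_nsnp`, `repl_beta`, `repl_se`, `repl_p` columns filled in.
#' @export
replicate_calls <- function(calls, validation_exposures, outcome,
                            config = attr(calls, "config") %||% default_config()) {
  stopifnot(inherits(calls, "causal_calls"))
  calls$repl_nsnp <- NA_integer_
  calls$repl_beta <- NA_real_
  calls$repl_se <- NA_real_
  calls$repl_p <- NA_real_
  for (i in seq_len(nrow(calls))) {
    if (!isTRUE(calls$discovery_pass[i])) next
    id <- calls$exposure_id[i]
    if (!id %in% names(validation_exposures)) {
      calls$replication_pass[i] <- NA  # unavailable
      next
    }
    rec <- .records_of(validation_exposures[[id]], id)$records
    h <- suppressWarnings(harmonize(
      structure(list(role = "exposure", id = id, records = rec,
                     rejects = NULL), class = "summary_stats"),
      outcome))
    h <- suppressWarnings(
      filter_outcome_significant(h, threshold = config$p_outcome_exclude))
    if (nrow(h$snps) < 2) {
      calls$replication_pass[i] <- FALSE
      next
    }
    ivw <- mr_ivw(h, mode = config$ivw_mode, ci_level = config$ci_level)
    ok <- ivw$pvalue < config$p_causal
    if (config$require_direction_replication) {
      ok <- ok && sign(ivw$beta) == sign(calls$ivw_beta[i])
    }
    calls$replication_pass[i] <- ok
    calls$repl_nsnp[i] <- ivw$nsnp
    calls$repl_beta[i] <- ivw$beta
    calls$repl_se[i] <- ivw$se
    calls$repl_p[i] <- ivw$pvalue
  }
  calls$high_confidence <- isTRUE_vec(calls$discovery_pass) &
    isTRUE_vec(calls$replication_pass)
  calls
}

# Elementwise isTRUE: NA -> FALSE.
isTRUE_vec <- function(x) !is.na(x) & x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Union of discovery-passing exposures across outcomes
#'
#' Collects the exposures with `discovery_pass = TRUE` in any outcome and
#' returns per-outcome membership flags — the set a multi-consortium analysis
#' carries forward.
#'
#' @param calls_by_outcome named list of `causal_calls`, one per outcome.
#' @return data frame with `exposure_id` and one logical column per outcome;
#'   zero rows when nothing passes anywhere.
#' @export
intersect_causal <- function(calls_by_outcome) {
  if (length(calls_by_outcome) == 0) stop("at least one outcome required")
  passers <- lapply(calls_by_outcome, function(cc) {
    cc$exposure_id[isTRUE_vec(cc$discovery_pass)]
  })
  union_ids <- sort(unique(unlist(passers)))
  out <- data.frame(exposure_id = union_ids, stringsAsFactors = FALSE)
  for (oid in names(calls_by_outcome)) {
    out[[oid]] <- union_ids %in% passers[[oid]]
  }
  out
}
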