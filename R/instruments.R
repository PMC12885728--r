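#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min over k >= i of m * p_(k) / k, capped at
#' 1, mapped back to input order. Delegates to [stats::p.adjust()] after
#' domain validation.
#'
#' @param pvalues numeric vector with all values in (0, 1].
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-SNP instrument-strength F statistic
#'
#' Summary-data approximation `F = (beta / se)^2`. Values above 10 are the
#' conventional threshold for a strong instrument.
#'
#' @param beta_gamma SNP-exposure effect(s).
#' @param se_gamma standard error(s), strictly positive.
#' @return numeric vector of F statistics.
#' @export
#' @examples
#' f_statistic(0.5, 0.1) # 25
f_statistic <- function(beta_gamma, se_gamma) {
  if (any(is.na(se_gamma)) || any(se_gamma <= 0)) stop("se_gamma must be > 0")
  (beta_gamma / se_gamma)^2
}

#' Select genetic instruments from exposure summary statistics
#'
#' Applies, in order: a cis filter (keep cis-eQTLs only), exclusion of coding
#' consequences (default synonymous/missense, to limit pleiotropy through
#' protein-altering effects), Benjamini-Hochberg FDR over the survivors'
#' p-values with `q < fdr_threshold`, and an instrument-strength filter
#' `F > f_threshold`. The cis and consequence filters are skipped with a
#' warning when the corresponding annotation is absent (validation-cohort
#' exports typically lack it). Output records are ordered by
#' (chrom, pos, rsid) so the result is independent of input order.
#'
#' @param records exposure records data frame (or `summary_stats` object).
#' @param fdr_threshold keep `q < fdr_threshold` (default 0.1).
#' @param f_threshold keep `F > f_threshold` (default 10).
#' @param require_cis apply the cis filter when annotation is present.
#' @param excluded_consequences consequence annotations to exclude.
#' @return an object of class `instrument_set`: list with `exposure_id`,
#'   `records` (surviving rows), `qvalues` and `f_stats` (aligned to
#'   `records`), and `filter_log` (named removal counts in application order).
#' @export
filter_instruments <- function(records, fdr_threshold = 0.1, f_threshold = 10,
                               require_cis = TRUE,
                               excluded_consequences = c("synonymous", "missense")) {
  ex <- .records_of(records, "exposure")
  rec <- ex$records
  log <- c(cis = 0L, consequence = 0L, fdr = 0L, f_stat = 0L)

  if (require_cis) {
    if (all(is.na(rec$cis))) {
      warning("cis annotation absent; cis filter skipped for ", ex$id)
    } else {
      keep <- !is.na(rec$cis) & rec$cis
      log["cis"] <- sum(!keep)
      rec <- rec[keep, , drop = FALSE]
    }
  }
  if (length(excluded_consequences) > 0) {
    if (all(is.na(rec$consequence))) {
      warning("consequence annotation absent; consequence filter skipped for ",
              ex$id)
    } else {
      keep <- is.na(rec$consequence) |
        !(tolower(rec$consequence) %in% tolower(excluded_consequences))
      log["consequence"] <- sum(!keep)
      rec <- rec[keep, , drop = FALSE]
    }
  }

  q <- if (nrow(rec) > 0) bh_fdr(rec$pvalue) else numeric(0)
  keep <- q < fdr_threshold
  log["fdr"] <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  q <- q[keep]

  f <- if (nrow(rec) > 0) f_statistic(rec$beta, rec$se) else numeric(0)
  keep <- f > f_threshold
  log["f_stat"] <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  q <- q[keep]
  f <- f[keep]

  ord <- order(rec$chrom, rec$pos, rec$rsid)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(exposure_id = ex$id, records = rec, qvalues = q[ord],
                 f_stats = f[ord], filter_log = log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for", x$exposure_id, "-", nrow(x$records),
      "SNPs retained\n")
  cat("  removed:", paste(names(x$filter_log), x$filter_log, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

# Normalize an LD source into a lookup function(rsid_a, rsid_b) -> r2.
.ld_lookup <- function(ld_r2) {
  if (is.function(ld_r2)) return(ld_r2)
  if (is.matrix(ld_r2)) {
    m <- ld_r2
    return(function(a, b) {
      if (a %in% rownames(m) && b %in% colnames(m)) m[a, b] else 0
    })
  }
  stop("ld_r2 must be a function(rsid_a, rsid_b) or a named square matrix")
}

#' Greedy LD clumping of candidate instruments
#'
#' Iterates records by ascending p-value (ties broken by chrom, pos, rsid) and
#' keeps a record iff no already-kept record on the same chromosome lies
#' within `window_bp` of it AND has `r^2 >= r2_threshold` with it — both
#' conditions must hold to prune, so distant correlated SNPs and nearby
#' uncorrelated SNPs are all retained. Defaults reproduce a liberal clump
#' (r^2 < 0.5 within 10 kb).
#'
#' @param records exposure records data frame (or `summary_stats` /
#'   `instrument_set` object).
#' @param ld_r2 pairwise r^2 source: a `function(rsid_a, rsid_b)` returning
#'   r^2 (0 when unknown), or a named square matrix. See [read_ld()].
#' @param r2_threshold prune at `r^2 >= r2_threshold` (default 0.5).
#' @param window_bp window in base pairs (default 10000).
#' @return the kept records, ordered by (chrom, pos).
#' @export
ld_clump <- function(records, ld_r2, r2_threshold = 0.5, window_bp = 10000) {
  if (inherits(records, "instrument_set")) records <- records$records
  rec <- .records_of(records, "exposure")$records
  if (r2_threshold < 0 || r2_threshold > 1) stop("r2_threshold must be in [0, 1]")
  if (window_bp < 0) stop("window_bp must be non-negative")
  lookup <- .ld_lookup(ld_r2)

  ord <- order(rec$pvalue, rec$chrom, rec$pos, rec$rsid)
  rec <- rec[ord, , drop = FALSE]
  kept <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    prior <- which(kept & rec$chrom == rec$chrom[i] &
                     abs(rec$pos - rec$pos[i]) <= window_bp)
    prior <- setdiff(prior, i)
    pruned <- FALSE
    for (j in prior) {
      if (lookup(rec$rsid[i], rec$rsid[j]) >= r2_threshold) {
        pruned <- TRUE
        break
      }
    }
    kept[i] <- !pruned
  }
  out <- rec[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pairwise LD (r-squared) table
#'
#' Accepts either a square matrix TSV (rsid header row and first column) or a
#' long-format triplet TSV with columns `rsid_a`, `rsid_b`, `r2`. Returns a
#' symmetric lookup function; pairs absent from the file default to r^2 = 0.
#'
#' @param path TSV path.
#' @return `function(rsid_a, rsid_b) -> r2`.
#' @export
read_ld <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (all(c("rsid_a", "rsid_b", "r2") %in% header)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
    env <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(tab))) {
      assign(key(tab$rsid_a[i], tab$rsid_b[i]), tab$r2[i], envir = env)
    }
    function(a, b) {
      v <- mget(key(a, b), envir = env, ifnotfound = list(0))[[1]]
      as.numeric(v)
    }
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
    .ld_lookup(m)
  }
}

#' Remove SNPs genome-wide significant for the outcome
#'
#' Drops harmonized SNPs whose outcome association p-value is at or below
#' `threshold` (default 5e-8), so that instruments retained are not themselves
#' genome-wide significant outcome loci; dropped SNPs are logged with reason
#' `"outcome genome-wide significant"`.
#'
#' @param harmonized a `harmonized_set`.
#' @param outcome_pvalues outcome p-values aligned with `harmonized$snps`; if
#'   `NULL`, the `pvalue_Gamma` column carried through harmonization is used.
#' @param threshold significance cutoff (default 5e-8).
#' @return the filtered `harmonized_set`.
#' @export
filter_outcome_significant <- function(harmonized, outcome_pvalues = NULL,
                                       threshold = 5e-8) {
  stopifnot(inherits(harmonized, "harmonized_set"))
  if (is.null(outcome_pvalues)) outcome_pvalues <- harmonized$snps$pvalue_Gamma
  if (length(outcome_pvalues) != nrow(harmonized$snps)) {
    stop("outcome_pvalues length (", length(outcome_pvalues),
         ") does not match number of harmonized SNPs (",
         nrow(harmonized$snps), ")")
  }
  drop <- !is.na(outcome_pvalues) & outcome_pvalues <= threshold
  if (any(drop)) {
    harmonized$dropped <- rbind(
      harmonized$dropped,
      data.frame(rsid = harmonized$snps$rsid[drop],
                 reason = "outcome genome-wide significant",
                 stringsAsFactors = FALSE)
    )
    harmonized <- subset_harmonized(harmonized, !drop)
  }
  if (nrow(harmonized$snps) == 0) {
    warning("no SNPs remain after outcome-significance filter for ",
            harmonized$exposure_id)
  }
  harmonized
}
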