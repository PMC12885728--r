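#' Default column mapping for summary-statistic tables
#'
#' Maps the package's standard field names to source column names. The default
#' matches the IEU OpenGWAS export header (`SNP`, `chr`, `pos`,
#' `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `eaf`). Optional
#' fields (`eaf`, `n`, `consequence`, `cis`, `id`) are used when present in the
#' file and silently skipped otherwise.
#'
#' @param ... named overrides, e.g. `rsid = "variant_id"`.
#' @return named list mapping standard field name to source column name.
#' @export
#' @examples
#' default_dialect(pvalue = "p")
default_dialect <- function(...) {
  d <- list(
    rsid = "SNP", chrom = "chr", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    beta = "beta", se = "se", pvalue = "pval",
    eaf = "eaf", n = "n", consequence = "consequence", cis = "cis", id = "id"
  )
  ov <- list(...)
  d[names(ov)] <- ov
  d
}

.mandatory_fields <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                       "beta", "se", "pvalue")

#' Test whether an allele pair is palindromic
#'
#' A palindromic (strand-ambiguous) SNP carries the allele pair A/T or C/G,
#' which is identical to its reverse complement; such SNPs cannot be aligned
#' between two studies without strand information and are removed during
#' harmonization.
#'
#' @param effect_allele,other_allele character vectors of single bases
#'   (A, C, G or T; case-insensitive).
#' @return logical vector.
#' @export
#' @examples
#' is_palindromic(c("A", "C", "A"), c("T", "G", "G"))
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  ok <- ea %in% c("A", "C", "G", "T") & oa %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    stop("non-ACGT allele passed to is_palindromic(): ",
         paste(unique(c(ea[!ok], oa[!ok])), collapse = ", "))
  }
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

.valid_allele <- function(x) toupper(x) %in% c("A", "C", "G", "T")

#' Read a summary-statistics table
#'
#' Reads a delimited text table (tab or comma, auto-detected from the header
#' line) of per-SNP association summary statistics for either an exposure
#' (miRNA-eQTL) or an outcome (disease GWAS) dataset. Rows failing basic
#' validity checks are rejected, each with a reason, and collected into a parse
#' report rather than aborting the read.
#'
#' Rejection reasons: missing beta or SE, `se <= 0`, multi-nucleotide or
#' non-ACGT alleles, identical effect/other alleles, p-value outside (0, 1],
#' missing rsid/position.
#'
#' @param path file path.
#' @param role `"exposure"` or `"outcome"`.
#' @param dialect column mapping, see [default_dialect()].
#' @param id dataset identifier (miRNA name or GWAS id); if `NULL`, taken from
#'   the mapped `id` column when present, else `basename(path)`.
#' @return an object of class `summary_stats`: a list with elements `role`,
#'   `id`, `records` (data frame with standardized columns `rsid`, `chrom`,
#'   `pos`, `ea`, `oa`, `beta`, `se`, `pvalue`, `eaf`, `n`, `consequence`,
#'   `cis`) and `rejects` (data frame `row`, `rsid`, `reason`).
#' @export
read_summary_table <- function(path, role = c("exposure", "outcome"),
                               dialect = default_dialect(), id = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("summary table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  missing_cols <- setdiff(unlist(dialect[.mandatory_fields]), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  get_col <- function(field, default = NA) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    rsid = as.character(get_col("rsid")),
    chrom = as.character(get_col("chrom")),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    ea = toupper(as.character(get_col("effect_allele"))),
    oa = toupper(as.character(get_col("other_allele"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    consequence = as.character(get_col("consequence")),
    cis = as.logical(get_col("cis")),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  flag(is.na(rec$rsid) | rec$rsid == "", "missing rsid")
  flag(is.na(rec$pos), "missing or non-integer position")
  flag(nchar(rec$ea) != 1 | nchar(rec$oa) != 1, "multi-nucleotide allele")
  flag(!.valid_allele(rec$ea) | !.valid_allele(rec$oa), "non-ACGT allele")
  flag(rec$ea == rec$oa, "identical alleles")
  flag(is.na(rec$beta), "missing beta")
  flag(is.na(rec$se), "missing SE")
  flag(rec$se <= 0, "non-positive SE")
  flag(is.na(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1,
       "p-value outside (0, 1]")

  bad <- !is.na(reason)
  rejects <- data.frame(row = which(bad), rsid = rec$rsid[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  records <- rec[!bad, , drop = FALSE]
  rownames(records) <- NULL
  if (nrow(records) == 0) stop("no valid rows in ", path)

  if (is.null(id)) {
    idc <- get_col("id")
    id <- if (!all(is.na(idc))) as.character(idc[!is.na(idc)][1]) else basename(path)
  }
  structure(list(role = role, id = id, records = records, rejects = rejects),
            class = "summary_stats")
}

# Accept either a summary_stats object or a bare records data frame.
.records_of <- function(x, default_id) {
  if (inherits(x, "summary_stats")) list(records = x$records, id = x$id)
  else if (is.data.frame(x)) list(records = x, id = default_id)
  else stop("expected a summary_stats object or a records data frame")
}

# Keep one row per rsid (smallest p-value, ties by chrom/pos); return kept rows
# and a drop log for the rest.
.dedupe_rsid <- function(rec) {
  ord <- order(rec$pvalue, rec$chrom, rec$pos, rec$rsid)
  rec <- rec[ord, , drop = FALSE]
  dup <- duplicated(rec$rsid)
  list(records = rec[!dup, , drop = FALSE],
       dropped = data.frame(rsid = rec$rsid[dup],
                            reason = rep("duplicate", sum(dup)),
                            stringsAsFactors = FALSE))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele, SNP by SNP, matching
#' on rsid. Matches whose outcome alleles equal the exposure's are kept as-is;
#' matches with swapped effect/other alleles have the outcome beta negated and
#' are flagged `flipped`; inconsistent allele sets are dropped with reason
#' `"allele mismatch"`. All palindromic SNPs (A/T or C/G) are dropped
#' unconditionally with reason `"palindromic"` — no allele-frequency rescue.
#' Duplicate rsids within a table are resolved beforehand by keeping the row
#' with the smallest p-value (the rest logged as dropped `"duplicate"`).
#' Position disagreement at a matching rsid is reported as a warning (genome
#' builds differ), not a drop. Output is ordered by (chrom, pos, rsid) for
#' reproducibility.
#'
#' @param exposure,outcome `summary_stats` objects (or bare records data
#'   frames) for a single exposure and a single outcome.
#' @return an object of class `harmonized_set`: list with `exposure_id`,
#'   `outcome_id`, `snps` (data frame `rsid`, `chrom`, `pos`, `ea`, `oa`,
#'   `gamma`, `se_gamma`, `Gamma`, `se_Gamma`, `pvalue_gamma`, `pvalue_Gamma`,
#'   `flipped`), `dropped` (data frame `rsid`, `reason`) and `n_matched`
#'   (number of rsid matches). Zero surviving SNPs is returned (with a
#'   warning), not an error; downstream estimators enforce their own minima.
#' @export
harmonize <- function(exposure, outcome) {
  ex <- .records_of(exposure, "exposure")
  ou <- .records_of(outcome, "outcome")
  exd <- .dedupe_rsid(ex$records)
  oud <- .dedupe_rsid(ou$records)
  e <- exd$records
  o <- oud$records

  common <- intersect(e$rsid, o$rsid)
  e <- e[match(common, e$rsid), , drop = FALSE]
  o <- o[match(common, o$rsid), , drop = FALSE]
  n_matched <- length(common)

  pos_mismatch <- !is.na(e$pos) & !is.na(o$pos) & e$pos != o$pos
  if (any(pos_mismatch)) {
    warning(sum(pos_mismatch), " matched rsid(s) disagree on position ",
            "(genome builds may differ); kept, matched by rsid")
  }

  pal <- is_palindromic(e$ea, e$oa)
  same <- o$ea == e$ea & o$oa == e$oa
  swapped <- o$ea == e$oa & o$oa == e$ea
  keep <- !pal & (same | swapped)

  reason <- character(n_matched)
  reason[pal] <- "palindromic"
  reason[!pal & !(same | swapped)] <- "allele mismatch"

  Gamma <- ifelse(swapped, -o$beta, o$beta)
  snps <- data.frame(
    rsid = e$rsid, chrom = e$chrom, pos = e$pos, ea = e$ea, oa = e$oa,
    gamma = e$beta, se_gamma = e$se,
    Gamma = Gamma, se_Gamma = o$se,
    pvalue_gamma = e$pvalue, pvalue_Gamma = o$pvalue,
    flipped = swapped, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  snps <- snps[order(snps$chrom, snps$pos, snps$rsid), , drop = FALSE]
  rownames(snps) <- NULL

  dropped <- rbind(
    data.frame(rsid = e$rsid[!keep], reason = reason[!keep],
               stringsAsFactors = FALSE),
    exd$dropped, oud$dropped
  )
  if (nrow(snps) == 0) warning("harmonization produced zero SNPs for ",
                               ex$id, " vs ", ou$id)
  structure(list(exposure_id = ex$id, outcome_id = ou$id, snps = snps,
                 dropped = dropped, n_matched = n_matched),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set:", x$exposure_id, "on", x$outcome_id, "\n")
  cat(" ", nrow(x$snps), "SNPs retained of", x$n_matched, "rsid matches;",
      sum(x$snps$flipped), "flipped;", nrow(x$dropped), "dropped\n")
  invisible(x)
}

# Subset a harmonized_set by row index, preserving metadata.
subset_harmonized <- function(h, idx) {
  h$snps <- h$snps[idx, , drop = FALSE]
  rownames(h$snps) <- NULL
  h
}

#' Write a harmonized set (and its drop log) to TSV
#'
#' Writes `rsid, chrom, pos, ea, oa, gamma, se_gamma, Gamma, se_Gamma, flipped`
#' to `path` and the drop log to `<path>.drops.tsv`.
#'
#' @param h a `harmonized_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  cols <- c("rsid", "chrom", "pos", "ea", "oa", "gamma", "se_gamma",
            "Gamma", "se_Gamma", "flipped")
  utils::write.table(h$snps[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(h$dropped, paste0(path, ".drops.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
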