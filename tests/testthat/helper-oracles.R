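# Independent oracles and fixture builders shared across test files.

# Build a harmonized_set directly from effect vectors.
make_h <- function(gamma, se_gamma, Gamma, se_Gamma,
                   exposure_id = "exp", outcome_id = "out",
                   chrom = "1", pvalue_Gamma = NULL) {
  J <- length(gamma)
  snps <- data.frame(
    rsid = sprintf("rs%03d", seq_len(J)), chrom = chrom,
    pos = as.integer(1000 * seq_len(J)), ea = "A", oa = "G",
    gamma = gamma, se_gamma = se_gamma, Gamma = Gamma, se_Gamma = se_Gamma,
    pvalue_gamma = 2 * pnorm(-abs(gamma / se_gamma)),
    pvalue_Gamma = if (is.null(pvalue_Gamma))
      2 * pnorm(-abs(Gamma / se_Gamma)) else pvalue_Gamma,
    flipped = FALSE, stringsAsFactors = FALSE
  )
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 snps = snps, dropped = data.frame(rsid = character(0),
                                                   reason = character(0)),
                 n_matched = J),
            class = "harmonized_set")
}

# Random harmonized fixture.
random_h <- function(J, seed) {
  set.seed(seed)
  make_h(gamma = rnorm(J, 0.2, 0.1), se_gamma = runif(J, 0.01, 0.05),
         Gamma = rnorm(J, 0, 0.05), se_Gamma = runif(J, 0.005, 0.03))
}

# Brute-force Benjamini-Hochberg: sort, scale, cumulative min from the tail.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Brute-force greedy clump: literal restatement of the rule, kept independent
# of the package implementation (explicit pairwise loop, no early exit).
clump_oracle <- function(rec, lookup, r2_threshold, window_bp) {
  ord <- order(rec$pvalue, rec$chrom, rec$pos, rec$rsid)
  rec <- rec[ord, , drop = FALSE]
  kept_idx <- integer(0)
  for (i in seq_len(nrow(rec))) {
    conflict <- FALSE
    for (j in kept_idx) {
      same_chr <- rec$chrom[i] == rec$chrom[j]
      in_window <- abs(rec$pos[i] - rec$pos[j]) <= window_bp
      correlated <- lookup(rec$rsid[i], rec$rsid[j]) >= r2_threshold
      if (same_chr && in_window && correlated) conflict <- TRUE
    }
    if (!conflict) kept_idx <- c(kept_idx, i)
  }
  sort(rec$rsid[kept_idx])
}

# Closed-form weighted least squares of G on g with intercept: normal
# equations solved explicitly (2x2), unscaled SEs, residual scale floored at 1.
wls_oracle <- function(g, G, w) {
  sw <- sum(w); swg <- sum(w * g); swg2 <- sum(w * g^2)
  swG <- sum(w * G); swgG <- sum(w * g * G)
  det <- sw * swg2 - swg^2
  a <- (swg2 * swG - swg * swgG) / det   # intercept
  b <- (sw * swgG - swg * swG) / det     # slope
  res <- G - a - b * g
  sigma2 <- sum(w * res^2) / (length(g) - 2)
  se_a <- sqrt(swg2 / det) * max(1, sqrt(sigma2))
  se_b <- sqrt(sw / det) * max(1, sqrt(sigma2))
  list(intercept = a, slope = b, se_intercept = se_a, se_slope = se_b)
}

# Closed-form IVW through the origin (fixed effect).
ivw_oracle <- function(g, G, w) {
  beta <- sum(w * g * G) / sum(w * g^2)
  list(beta = beta, se = sqrt(1 / sum(w * g^2)))
}

# Write a records data frame as an IEU-style TSV and return the path.
write_ieu_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Run the full fixture pipeline (instrument selection, clump, discovery on
# both outcomes, replication) and return the per-outcome calls.
run_fixture_pipeline <- function(fx, config = default_config()) {
  disc <- lapply(names(fx$discovery), function(id) {
    inst <- suppressWarnings(filter_instruments(
      fx$discovery[[id]], fdr_threshold = config$fdr_instrument,
      f_threshold = config$f_min))
    ld_clump(inst, fx$ld, r2_threshold = config$r2_clump,
             window_bp = config$window_bp)
  })
  names(disc) <- names(fx$discovery)
  val <- lapply(fx$validation, function(r) {
    r[r$pvalue < config$p_validation_instrument, , drop = FALSE]
  })
  calls <- lapply(names(fx$outcomes), function(oid) {
    cc <- run_discovery(disc, fx$outcomes[[oid]], outcome_id = oid,
                        config = config)
    replicate_calls(cc, val, fx$outcomes[[oid]], config = config)
  })
  names(calls) <- names(fx$outcomes)
  calls
}
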