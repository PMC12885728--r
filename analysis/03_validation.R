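#!/usr/bin/env Rscript
# Stage 3: independent-cohort replication and high-confidence calls.
#
# Re-runs the discovery fits (cheap, deterministic), then takes every
# discovery-passing exposure into the validation eQTL cohort: instruments are
# re-selected with the relaxed p < 1e-5 criterion (validation exports carry no
# cis/consequence annotation), re-harmonized against the same outcome GWAS,
# and refitted with IVW. A call is high confidence only when the validation
# IVW is significant with the discovery direction. Exposures missing from the
# validation cohort are reported as replication-unavailable.

suppressPackageStartupMessages(library(mirmr))

data_dir <- "results/data"
cfg <- default_config()

read_records <- function(pattern, prefix) {
  files <- list.files(data_dir, pattern = pattern, full.names = TRUE)
  recs <- lapply(files, read_summary_table, role = "exposure")
  names(recs) <- sub(paste0("^", prefix, "_(.*)\\.tsv$"), "\\1",
                     basename(files))
  recs
}
exposures <- read_records("^discovery_.*\\.tsv$", "discovery")
validation <- read_records("^validation_.*\\.tsv$", "validation")
ld <- read_ld(file.path(data_dir, "ld_triplets.tsv"))

instruments <- lapply(exposures, function(ss) {
  inst <- suppressWarnings(filter_instruments(
    ss$records, fdr_threshold = cfg$fdr_instrument, f_threshold = cfg$f_min))
  ld_clump(inst, ld, r2_threshold = cfg$r2_clump, window_bp = cfg$window_bp)
})
validation_instruments <- lapply(validation, function(ss) {
  keep <- ss$records$pvalue < cfg$p_validation_instrument
  ld_clump(ss$records[keep, , drop = FALSE], ld,
           r2_threshold = cfg$r2_clump, window_bp = cfg$window_bp)
})

outcome_files <- list.files(data_dir, pattern = "^outcome_.*\\.tsv$",
                            full.names = TRUE)
replicated <- list()
for (of in outcome_files) {
  oid <- sub("^outcome_(.*)\\.tsv$", "\\1", basename(of))
  outcome <- read_summary_table(of, role = "outcome", id = oid)
  calls <- run_discovery(instruments, outcome, outcome_id = oid, config = cfg)
  calls <- replicate_calls(calls, validation_instruments, outcome,
                           config = cfg)
  replicated[[oid]] <- calls
  for (i in which(!is.na(calls$discovery_pass) & calls$discovery_pass)) {
    status <- if (is.na(calls$replication_pass[i])) {
      "not covered by the validation cohort"
    } else if (calls$replication_pass[i]) {
      sprintf("replicated (validation IVW p = %.2e, %d SNPs)",
              calls$repl_p[i], calls$repl_nsnp[i])
    } else {
      "failed replication"
    }
    cat(sprintf("%s / %s: %s\n", oid, calls$exposure_id[i], status))
  }
}

out <- do.call(rbind, lapply(replicated, as.data.frame))
write.table(out, "results/validation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hc <- out[out$high_confidence, c("outcome_id", "exposure_id", "ivw_beta",
                                 "ivw_p", "repl_beta", "repl_p")]
cat("High-confidence causal calls:", nrow(hc), "\n")
if (nrow(hc) > 0) print(hc, row.names = FALSE)
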