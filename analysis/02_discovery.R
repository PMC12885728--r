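#!/usr/bin/env Rscript
# Stage 2: discovery-phase MR screening.
#
# Reads the exposure and outcome summary statistics written by stage 1,
# selects instruments (cis/consequence filters, BH FDR < 0.1, F > 10, greedy
# LD clumping at r2 < 0.5 within 10 kb), harmonizes each exposure against each
# outcome, and fits IVW and MR-Egger with the full sensitivity battery.
# Writes Table-style outputs: calls.tsv (per exposure x outcome),
# forest.tsv (estimate rows), sensitivity.tsv, loo.tsv.

suppressPackageStartupMessages(library(mirmr))

data_dir <- "results/data"
cfg <- default_config()

exposure_files <- list.files(data_dir, pattern = "^discovery_.*\\.tsv$",
                             full.names = TRUE)
exposures <- lapply(exposure_files, read_summary_table, role = "exposure")
names(exposures) <- sub("^discovery_(.*)\\.tsv$", "\\1",
                        basename(exposure_files))
ld <- read_ld(file.path(data_dir, "ld_triplets.tsv"))

instruments <- lapply(names(exposures), function(id) {
  inst <- suppressWarnings(filter_instruments(
    exposures[[id]]$records, fdr_threshold = cfg$fdr_instrument,
    f_threshold = cfg$f_min))
  cat(sprintf("%s: %d candidate SNPs -> %d instruments (removed %s)\n",
              id, nrow(exposures[[id]]$records), nrow(inst$records),
              paste(names(inst$filter_log), inst$filter_log, sep = "=",
                    collapse = ", ")))
  ld_clump(inst, ld, r2_threshold = cfg$r2_clump, window_bp = cfg$window_bp)
})
names(instruments) <- names(exposures)

outcome_files <- list.files(data_dir, pattern = "^outcome_.*\\.tsv$",
                            full.names = TRUE)
calls_by_outcome <- list()
for (of in outcome_files) {
  oid <- sub("^outcome_(.*)\\.tsv$", "\\1", basename(of))
  outcome <- read_summary_table(of, role = "outcome", id = oid)
  calls <- run_discovery(instruments, outcome, outcome_id = oid, config = cfg)
  calls_by_outcome[[oid]] <- calls
  hits <- calls$exposure_id[!is.na(calls$discovery_pass) & calls$discovery_pass]
  cat(sprintf("%s: %d/%d exposures pass discovery (%s)\n", oid,
              length(hits), nrow(calls),
              if (length(hits)) paste(hits, collapse = ", ") else "none"))
}

dir.create("results", showWarnings = FALSE)
all_calls <- do.call(rbind, lapply(calls_by_outcome, as.data.frame))
write.table(all_calls, "results/calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, lapply(calls_by_outcome, format_forest_table)),
            "results/forest.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, lapply(calls_by_outcome, format_sensitivity_table)),
            "results/sensitivity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, lapply(calls_by_outcome, format_loo_table)),
            "results/loo.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
u <- intersect_causal(calls_by_outcome)
cat("Union of discovery hits across outcomes:",
    paste(u$exposure_id, collapse = ", "), "\n")
write.table(u, "results/discovery_union.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
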