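#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the five-exposure / two-outcome / one-validation-cohort dataset whose
# construction mirrors the decision structure of a discovery-plus-replication
# miRNA MR study, and writes every table as a TSV that the downstream stages
# read back through the package's own readers.

suppressPackageStartupMessages(library(mirmr))

seed <- 20260925
out_dir <- "results/data"
fx <- make_paper_like_fixture(seed)
paths <- write_fixture(fx, out_dir)

# also persist the LD relation used for clumping (trivially independent here:
# the fixture spaces SNPs beyond the clumping window)
ld_path <- file.path(out_dir, "ld_triplets.tsv")
write.table(data.frame(rsid_a = character(0), rsid_b = character(0),
                       r2 = numeric(0)),
            ld_path, sep = "\t", quote = FALSE, row.names = FALSE)

write_run_manifest("results", list(stage = "simulate", seed = seed),
                   inputs = paths,
                   counts = c(exposures = length(fx$discovery),
                              validation_exposures = length(fx$validation),
                              outcomes = length(fx$outcomes)))

cat("Wrote", length(paths) + 1, "tables under", out_dir, "\n")
cat("Exposures:", paste(names(fx$discovery), collapse = ", "), "\n")
cat("Validation cohort covers:", paste(names(fx$validation), collapse = ", "),
    "\n")
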