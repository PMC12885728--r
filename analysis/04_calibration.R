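#!/usr/bin/env Rscript
# Stage 4: statistical calibration of the estimators on the generative model.
#
# Three simulation studies sized to run in seconds:
#   - type-I error of the (random-effects) IVW test under the null;
#   - recovery of a protective causal effect (beta = -0.3) by IVW;
#   - recovery of injected directional pleiotropy (0.02) by the Egger
#     intercept, with the Egger slope staying near the causal truth.

suppressPackageStartupMessages(library(mirmr))

seed <- 20260925

rej <- vapply(1:1000, function(i) {
  sim <- simulate_pair(sim_config(n_snps = 30, causal_beta = 0,
                                  seed = substream_seed(seed, paste0("n", i))))
  mr_ivw(harmonize(sim$exposure, sim$outcome))$pvalue < 0.05
}, logical(1))

recov <- vapply(1:500, function(i) {
  sim <- simulate_pair(sim_config(n_snps = 50, causal_beta = -0.3,
                                  n_exposure = 20000,
                                  seed = substream_seed(seed, paste0("r", i))))
  mr_ivw(harmonize(sim$exposure, sim$outcome))$beta
}, numeric(1))

pleio <- t(vapply(1:500, function(i) {
  sim <- simulate_pair(sim_config(n_snps = 100, causal_beta = -0.3,
                                  n_exposure = 20000, pleiotropy_mean = 0.02,
                                  seed = substream_seed(seed, paste0("p", i))))
  h <- harmonize(sim$exposure, sim$outcome)
  e <- mr_egger(h)
  c(intercept = e$intercept$beta, slope = e$slope$beta,
    ivw = mr_ivw(h)$beta)
}, numeric(3)))

tab <- data.frame(
  quantity = c("ivw_type1_error", "ivw_mean_estimate", "ivw_bias",
               "egger_intercept_mean", "egger_slope_mean",
               "ivw_mean_under_pleiotropy"),
  truth = c(0.05, -0.3, 0, 0.02, -0.3, -0.3),
  estimate = c(mean(rej), mean(recov), mean(recov) + 0.3,
               mean(pleio[, "intercept"]), mean(pleio[, "slope"]),
               mean(pleio[, "ivw"])),
  replicates = c(1000, 500, 500, 500, 500, 500)
)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/calibration.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nNote the directional-pleiotropy row: IVW absorbs the pleiotropic",
    "shift while the Egger intercept isolates it and the slope stays near",
    "the causal truth.\n")
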