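test_that("a well-formed exposure table reads cleanly and bad rows are rejected with reasons", {
  df <- data.frame(
    SNP = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    chr = "1", pos = 1:6 * 1000,
    effect_allele = c("A", "C", "G", "A", "A", "A"),
    other_allele = c("G", "T", "A", "AT", "G", "G"),
    beta = c(0.1, -0.2, 0.3, 0.1, NA, 0.2),
    se = c(0.05, 0.04, 0.03, 0.05, 0.05, -0.01),
    pval = c(1e-4, 1e-5, 1e-6, 1e-4, 1e-4, 1e-4)
  )
  ss <- read_summary_table(write_ieu_tsv(df), role = "exposure", id = "mirX")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss$records), 3)
  expect_equal(ss$records$rsid, c("rs1", "rs2", "rs3"))
  expect_setequal(ss$rejects$reason,
                  c("multi-nucleotide allele", "missing beta",
                    "non-positive SE"))
  expect_equal(ss$id, "mirX")
})

test_that("a clean 3-row table yields 3 records and an empty reject list", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), chr = "2", pos = 1:3,
                   effect_allele = "A", other_allele = "C",
                   beta = 0.1, se = 0.02, pval = 0.001)
  ss <- read_summary_table(write_ieu_tsv(df), role = "exposure")
  expect_equal(nrow(ss$records), 3)
  expect_equal(nrow(ss$rejects), 0)
})

test_that("missing mandatory columns and empty tables are errors", {
  df <- data.frame(SNP = "rs1", chr = "1", pos = 1,
                   effect_allele = "A", other_allele = "C",
                   beta = 0.1, se = 0.02)
  expect_error(read_summary_table(write_ieu_tsv(df), "exposure"),
               "mandatory column")
  df2 <- data.frame(SNP = "rs1", chr = "1", pos = 1,
                    effect_allele = "AA", other_allele = "C",
                    beta = 0.1, se = 0.02, pval = 0.5)
  expect_error(read_summary_table(write_ieu_tsv(df2), "exposure"),
               "no valid rows")
})

test_that("simulated tables round-trip through write and read unchanged", {
  sim <- simulate_pair(sim_config(n_snps = 12, seed = 5,
                                  palindromic_frac = 0.25))
  paths <- write_simulated_pair(sim, tempdir(), prefix = "rt")
  back <- read_summary_table(paths[1], role = "exposure")
  expect_equal(nrow(back$rejects), 0)
  for (col in c("rsid", "chrom", "pos", "ea", "oa")) {
    expect_equal(back$records[[col]], sim$exposure$records[[col]])
  }
  for (col in c("beta", "se", "pvalue", "eaf")) {
    expect_equal(back$records[[col]], sim$exposure$records[[col]],
                 tolerance = 1e-12)
  }
})

test_that("palindromic allele pairs are exactly A/T and C/G", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("T", "C"))
  expect_error(is_palindromic("A", "N"), "non-ACGT")
})

test_that("harmonize keeps aligned SNPs, flips swapped alleles, drops mismatches and palindromes", {
  ex <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
                   pos = c(100L, 200L, 300L, 400L),
                   ea = c("A", "A", "A", "A"), oa = c("G", "G", "C", "T"),
                   beta = 0.5, se = 0.05, pvalue = 1e-6,
                   stringsAsFactors = FALSE)
  ou <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"), chrom = "1",
                   pos = c(100L, 200L, 300L, 400L),
                   ea = c("A", "G", "T", "A"), oa = c("G", "A", "C", "T"),
                   beta = 0.1, se = 0.02, pvalue = 0.5,
                   stringsAsFactors = FALSE)
  h <- harmonize(ex, ou)
  expect_equal(h$snps$rsid, c("rs1", "rs2"))
  expect_equal(h$snps$Gamma, c(0.1, -0.1))
  expect_equal(h$snps$flipped, c(FALSE, TRUE))
  expect_setequal(h$dropped$reason, c("allele mismatch", "palindromic"))
  expect_equal(h$n_matched, 4)
  # retained + dropped-at-match accounts for every rsid match
  match_stage <- h$dropped$reason %in% c("allele mismatch", "palindromic")
  expect_equal(nrow(h$snps) + sum(match_stage), h$n_matched)
})

test_that("harmonize is idempotent on already-aligned inputs", {
  sim <- simulate_pair(sim_config(n_snps = 20, seed = 9,
                                  palindromic_frac = 0.3))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # re-harmonize: use the harmonized set itself as both tables
  ex2 <- data.frame(rsid = h1$snps$rsid, chrom = h1$snps$chrom,
                    pos = h1$snps$pos, ea = h1$snps$ea, oa = h1$snps$oa,
                    beta = h1$snps$gamma, se = h1$snps$se_gamma,
                    pvalue = h1$snps$pvalue_gamma, stringsAsFactors = FALSE)
  ou2 <- data.frame(rsid = h1$snps$rsid, chrom = h1$snps$chrom,
                    pos = h1$snps$pos, ea = h1$snps$ea, oa = h1$snps$oa,
                    beta = h1$snps$Gamma, se = h1$snps$se_Gamma,
                    pvalue = h1$snps$pvalue_Gamma, stringsAsFactors = FALSE)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$snps$rsid, h1$snps$rsid)
  expect_equal(h2$snps$gamma, h1$snps$gamma)
  expect_equal(h2$snps$Gamma, h1$snps$Gamma)
  expect_false(any(h2$snps$flipped))
  expect_equal(nrow(h2$dropped), 0)
})

test_that("harmonization is an involution under outcome allele recoding", {
  for (seed in c(3, 17, 51)) {
    sim <- simulate_pair(sim_config(n_snps = 15, seed = seed,
                                    palindromic_frac = 0.2))
    h_ref <- harmonize(sim$exposure, sim$outcome)
    flipped <- sim$outcome
    flipped$records <- within(flipped$records, {
      tmp <- ea; ea <- oa; oa <- tmp; rm(tmp); beta <- -beta
    })
    h_flip <- harmonize(sim$exposure, flipped)
    expect_equal(h_flip$snps$gamma, h_ref$snps$gamma)
    expect_equal(h_flip$snps$Gamma, h_ref$snps$Gamma)
    expect_equal(h_flip$snps$rsid, h_ref$snps$rsid)
  }
})

test_that("no palindromic pair survives harmonization for random allele draws", {
  for (seed in 1:10) {
    sim <- simulate_pair(sim_config(n_snps = 30, seed = seed,
                                    palindromic_frac = 0.5))
    h <- harmonize(sim$exposure, sim$outcome)
    expect_false(any(is_palindromic(h$snps$ea, h$snps$oa)))
  }
})

test_that("duplicate rsids keep the smallest p-value and log the rest", {
  ex <- data.frame(rsid = c("rs1", "rs1", "rs2"), chrom = "1",
                   pos = c(100L, 100L, 200L), ea = "A", oa = "G",
                   beta = c(0.5, 0.9, 0.3), se = 0.05,
                   pvalue = c(1e-8, 1e-3, 1e-5), stringsAsFactors = FALSE)
  ou <- data.frame(rsid = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
                   ea = "A", oa = "G", beta = 0.1, se = 0.02, pvalue = 0.5,
                   stringsAsFactors = FALSE)
  h <- harmonize(ex, ou)
  expect_equal(nrow(h$snps), 2)
  expect_equal(h$snps$gamma[h$snps$rsid == "rs1"], 0.5)
  expect_true("duplicate" %in% h$dropped$reason)
})

test_that("harmonized sets serialize to TSV with a drop-log sidecar", {
  sim <- simulate_pair(sim_config(n_snps = 8, seed = 2,
                                  palindromic_frac = 0.3))
  h <- harmonize(sim$exposure, sim$outcome)
  path <- tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(h$snps))
  expect_equal(back$gamma, h$snps$gamma, tolerance = 1e-12)
  drops <- read.table(paste0(path, ".drops.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(drops), nrow(h$dropped))
})
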