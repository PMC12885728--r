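test_that("bh_fdr matches hand-computed and brute-force adjustments", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.42), 0.42)
  set.seed(101)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("F statistics follow the summary-data formula with a strict domain", {
  expect_equal(f_statistic(0.5, 0.1), 25)
  expect_equal(f_statistic(0, 0.1), 0)
  expect_equal(f_statistic(-0.3162278, 0.1), 10, tolerance = 1e-6)
  expect_error(f_statistic(0.5, 0), "> 0")
})

test_that("filter_instruments applies cis, consequence, FDR and F stages in order", {
  rec <- data.frame(
    rsid = sprintf("rs%d", 1:10), chrom = "1", pos = 1:10 * 1000L,
    ea = "A", oa = "G",
    beta = c(rep(0.5, 8), 0.01, 0.5), se = 0.05,
    pvalue = c(1e-10, 1e-10, 1e-9, 1e-9, 0.8, 0.9, 1e-8, 1e-8, 1e-8, 1e-8),
    eaf = 0.3, n = 5000,
    consequence = c("intergenic", "missense", rep("intergenic", 8)),
    cis = c(TRUE, TRUE, FALSE, rep(TRUE, 7)),
    stringsAsFactors = FALSE
  )
  inst <- filter_instruments(rec)
  expect_s3_class(inst, "instrument_set")
  expect_equal(unname(inst$filter_log),
               c(1L, 1L, 2L, 1L))  # cis, consequence, fdr, weak F
  expect_false("rs2" %in% inst$records$rsid)  # missense
  expect_false("rs3" %in% inst$records$rsid)  # trans
  expect_false("rs9" %in% inst$records$rsid)  # F = 0.04
  expect_true(all(inst$qvalues < 0.1))
  expect_true(all(inst$f_stats > 10))
  expect_equal(length(inst$qvalues), nrow(inst$records))
})

test_that("filter_instruments is insensitive to input row order", {
  sim <- simulate_pair(sim_config(n_snps = 25, seed = 31))
  rec <- sim$exposure$records
  a <- filter_instruments(rec)
  set.seed(1)
  b <- filter_instruments(rec[sample(nrow(rec)), ])
  expect_equal(a$records, b$records)
  expect_equal(a$qvalues, b$qvalues)
})

test_that("annotation-free tables skip cis/consequence filters with a warning", {
  rec <- data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = "1",
                    pos = 1:3 * 1000L, ea = "A", oa = "G", beta = 0.5,
                    se = 0.05, pvalue = 1e-10,
                    consequence = NA_character_, cis = NA,
                    stringsAsFactors = FALSE)
  expect_warning(expect_warning(inst <- filter_instruments(rec), "cis"),
                 "consequence")
  expect_equal(nrow(inst$records), 3)
})

test_that("greedy clumping prunes only same-chromosome pairs that are both close and correlated", {
  rec <- data.frame(rsid = c("rsA", "rsB", "rsC", "rsD"), chrom = "1",
                    pos = c(10000L, 15000L, 65000L, 70000L),
                    ea = "A", oa = "G", beta = 0.5, se = 0.05,
                    pvalue = c(1e-10, 1e-5, 1e-8, 1e-6),
                    stringsAsFactors = FALSE)
  r2 <- function(a, b) 0.9  # everything correlated
  kept <- ld_clump(rec, r2, r2_threshold = 0.5, window_bp = 10000)
  # rsB pruned by rsA (5 kb, r2 .9); rsD pruned by rsC; rsC kept (55 kb from rsA)
  expect_equal(kept$rsid, c("rsA", "rsC"))
  # distant pair survives regardless of r2
  kept2 <- ld_clump(rec[c(1, 3), ], r2, 0.5, 10000)
  expect_equal(nrow(kept2), 2)
  # uncorrelated near pair survives
  kept3 <- ld_clump(rec[1:2, ], function(a, b) 0.1, 0.5, 10000)
  expect_equal(nrow(kept3), 2)
  expect_error(ld_clump(rec, r2, r2_threshold = 1.5), "r2_threshold")
  expect_error(ld_clump(rec, r2, window_bp = -1), "window_bp")
})

test_that("clumping matches the brute-force greedy oracle on random block-LD fixtures", {
  for (seed in 1:25) {
    cfg <- sim_config(n_snps = sample(4:12, 1), ld_block_size = sample(2:4, 1),
                      ld_rho = runif(1, 0.4, 0.95), spacing_bp = 4000,
                      seed = seed)
    sim <- simulate_pair(cfg)
    rec <- sim$exposure$records
    thr <- runif(1, 0.2, 0.8)
    win <- sample(c(4000L, 8000L, 16000L), 1)
    kept <- ld_clump(rec, sim$ld, r2_threshold = thr, window_bp = win)
    expect_equal(sort(kept$rsid), clump_oracle(rec, sim$ld, thr, win))
    # antichain validity: no kept pair is jointly within-window and correlated
    if (nrow(kept) > 1) {
      pairs <- combn(nrow(kept), 2)
      viol <- apply(pairs, 2, function(ij) {
        i <- ij[1]; j <- ij[2]
        kept$chrom[i] == kept$chrom[j] &&
          abs(kept$pos[i] - kept$pos[j]) <= win &&
          sim$ld(kept$rsid[i], kept$rsid[j]) >= thr
      })
      expect_false(any(viol))
    }
  }
})

test_that("degenerate clump settings keep every record", {
  sim <- simulate_pair(sim_config(n_snps = 10, ld_block_size = 5,
                                  ld_rho = 0.9, spacing_bp = 100, seed = 8))
  rec <- sim$exposure$records
  expect_equal(nrow(ld_clump(rec, sim$ld, r2_threshold = 1.0,
                             window_bp = 10000)), 10)
  expect_equal(nrow(ld_clump(rec, sim$ld, r2_threshold = 0.1,
                             window_bp = 0)), 10)
})

test_that("LD tables read as symmetric lookups defaulting to zero", {
  trip <- data.frame(rsid_a = c("rs1", "rs2"), rsid_b = c("rs2", "rs3"),
                     r2 = c(0.8, 0.3))
  path <- tempfile(fileext = ".tsv")
  write.table(trip, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lk <- read_ld(path)
  expect_equal(lk("rs1", "rs2"), 0.8)
  expect_equal(lk("rs2", "rs1"), 0.8)
  expect_equal(lk("rs1", "rs3"), 0)
  m <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(c("rs1", "rs2"),
                                                    c("rs1", "rs2")))
  mpath <- tempfile(fileext = ".tsv")
  write.table(m, mpath, sep = "\t", quote = FALSE, col.names = NA)
  lk2 <- read_ld(mpath)
  expect_equal(lk2("rs1", "rs2"), 0.7)
})

test_that("outcome genome-wide-significant SNPs are excluded with a logged reason", {
  h <- make_h(gamma = c(0.5, 0.4, 0.3), se_gamma = 0.05,
              Gamma = c(0.1, 0.05, 0.02), se_Gamma = 0.02)
  unchanged <- filter_outcome_significant(h, rep(0.5, 3))
  expect_equal(nrow(unchanged$snps), 3)
  one_out <- filter_outcome_significant(h, c(1e-9, 0.5, 0.5))
  expect_equal(nrow(one_out$snps), 2)
  expect_true("outcome genome-wide significant" %in% one_out$dropped$reason)
  expect_warning(all_out <- filter_outcome_significant(h, rep(0.5, 3),
                                                       threshold = 1.0),
                 "no SNPs remain")
  expect_equal(nrow(all_out$snps), 0)
  expect_error(filter_outcome_significant(h, c(0.5, 0.5)), "length")
})
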