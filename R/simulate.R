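#' Configuration for the synthetic summary-statistics generator
#'
#' Parameterizes a two-sample generative model: per-SNP minor allele
#' frequencies MAF_j ~ Uniform(maf_range); true instrument effects
#' gamma_j ~ Normal(gamma_mean, gamma_sd); exposure standard errors from the
#' standardized-trait approximation `1 / sqrt(2 n MAF (1 - MAF))`; outcome
#' standard errors from the logistic case-control approximation
#' `sqrt((1 / n_cases + 1 / n_controls) / (2 MAF (1 - MAF)))`; pleiotropic
#' effects `alpha_j = pleiotropy_mean + pleiotropy_sd * Z_j`, plus a term
#' proportional to gamma_j when `inside_violation` is set (breaking InSIDE);
#' observed effects are the truths plus Gaussian sampling noise at the stated
#' standard errors. LD is block-constant: r^2 = `ld_rho^2` within consecutive
#' blocks of `ld_block_size` SNPs, 0 across blocks.
#'
#' Default cohort sizes mirror a large case-control GWAS (35,102 cases /
#' 388,356 controls) paired with a population eQTL cohort of 5000.
#'
#' @param n_snps number of SNPs J.
#' @param n_exposure exposure-cohort sample size.
#' @param n_outcome_cases,n_outcome_controls outcome case-control sizes.
#' @param maf_range MAF bounds, within (0, 0.5].
#' @param gamma_mean,gamma_sd distribution of true instrument effects.
#' @param causal_beta true causal effect (log-OR per unit exposure).
#' @param pleiotropy_mean,pleiotropy_sd directional and balanced pleiotropy.
#' @param inside_violation correlate pleiotropy with instrument strength.
#' @param ld_block_size,ld_rho block LD structure.
#' @param spacing_bp fixed inter-SNP spacing on one chromosome.
#' @param palindromic_frac fraction of SNPs drawn with A/T or C/G alleles.
#' @param seed root seed; all draws flow from it through named substreams.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, n_exposure = 5000,
                       n_outcome_cases = 35102, n_outcome_controls = 388356,
                       maf_range = c(0.1, 0.5),
                       gamma_mean = 0.15, gamma_sd = 0.05,
                       causal_beta = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       inside_violation = FALSE,
                       ld_block_size = 1, ld_rho = 0,
                       spacing_bp = 20000, palindromic_frac = 0,
                       seed = 1) {
  stopifnot(n_snps >= 1, n_exposure >= 2, n_outcome_cases >= 2,
            n_outcome_controls >= 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            gamma_sd >= 0, pleiotropy_sd >= 0,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            spacing_bp >= 1, palindromic_frac >= 0, palindromic_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Derive a named substream seed from a root seed
#'
#' Deterministically maps a root seed and a stream name to an integer seed
#' below 2^31, so independent draw groups (and replicate loops) each get a
#' stable stream that does not shift when another group grows. Polynomial
#' string hash mixed with the seed modulo a prime below 2^31; all
#' intermediates stay exact in doubles (under 2^53).
#'
#' @param seed integer root seed.
#' @param name stream name.
#' @return integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' substream_seed(1, "maf")
substream_seed <- function(seed, name) {
  m <- 2147483629
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% m
  s <- abs(as.numeric(seed)) %% m
  as.integer((s * 48271 + h * 69621 + 12345) %% m)
}

.with_stream <- function(seed, name, expr) {
  set.seed(substream_seed(seed, name))
  expr
}

.nonpal_pairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)
.pal_pairs <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                     ncol = 2, byrow = TRUE)

# Shared variant scaffold: ids, positions, alleles, MAFs, true gammas.
.sim_variants <- function(config, chrom = "1", rsid_offset = 0L) {
  J <- config$n_snps
  maf <- .with_stream(config$seed, "maf",
                      stats::runif(J, config$maf_range[1], config$maf_range[2]))
  gamma_true <- .with_stream(config$seed, "gamma_true",
                             stats::rnorm(J, config$gamma_mean, config$gamma_sd))
  alleles <- .with_stream(config$seed, "alleles", {
    pal <- stats::runif(J) < config$palindromic_frac
    idx_np <- sample(nrow(.nonpal_pairs), J, replace = TRUE)
    idx_p <- sample(nrow(.pal_pairs), J, replace = TRUE)
    cbind(ifelse(pal, .pal_pairs[idx_p, 1], .nonpal_pairs[idx_np, 1]),
          ifelse(pal, .pal_pairs[idx_p, 2], .nonpal_pairs[idx_np, 2]))
  })
  data.frame(
    rsid = sprintf("rs%07d", rsid_offset + seq_len(J)),
    chrom = chrom,
    pos = as.integer(config$spacing_bp * seq_len(J)),
    ea = alleles[, 1], oa = alleles[, 2],
    maf = maf, gamma_true = gamma_true,
    stringsAsFactors = FALSE
  )
}

.se_exposure <- function(maf, n) 1 / sqrt(2 * n * maf * (1 - maf))
.se_outcome <- function(maf, n_cases, n_controls) {
  sqrt((1 / n_cases + 1 / n_controls) / (2 * maf * (1 - maf)))
}

# Observed exposure records from the variant scaffold.
.sim_exposure_obs <- function(variants, config, exposure_id, stream = "gamma_obs") {
  se <- .se_exposure(variants$maf, config$n_exposure)
  obs <- .with_stream(config$seed, stream,
                      stats::rnorm(nrow(variants), variants$gamma_true, se))
  data.frame(
    rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
    ea = variants$ea, oa = variants$oa,
    beta = obs, se = se, pvalue = mr_pvalue(obs, se),
    eaf = variants$maf, n = config$n_exposure,
    consequence = "intergenic", cis = TRUE,
    stringsAsFactors = FALSE
  )
}

# Observed outcome records; `residual` overrides the Gaussian noise with a
# deterministic vector in units of the outcome SE (used by fixtures).
.sim_outcome_obs <- function(variants, config, gamma_for_outcome,
                             stream = "Gamma_obs", residual = NULL) {
  J <- nrow(variants)
  se <- .se_outcome(variants$maf, config$n_outcome_cases,
                    config$n_outcome_controls)
  alpha <- .with_stream(config$seed, "pleiotropy", {
    a <- config$pleiotropy_mean + config$pleiotropy_sd * stats::rnorm(J)
    if (config$inside_violation) a <- a + 0.5 * variants$gamma_true
    a
  })
  mu <- config$causal_beta * gamma_for_outcome + alpha
  obs <- if (is.null(residual)) {
    .with_stream(config$seed, stream, stats::rnorm(J, mu, se))
  } else {
    mu + residual * se
  }
  data.frame(
    rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
    ea = variants$ea, oa = variants$oa,
    beta = obs, se = se, pvalue = mr_pvalue(obs, se),
    eaf = variants$maf,
    stringsAsFactors = FALSE
  )
}

.block_ld <- function(variants, config) {
  block <- ceiling(seq_len(nrow(variants)) / config$ld_block_size)
  names(block) <- variants$rsid
  rho2 <- config$ld_rho^2
  function(a, b) {
    if (!a %in% names(block) || !b %in% names(block)) return(0)
    if (a == b) return(1)
    if (block[[a]] == block[[b]]) rho2 else 0
  }
}

.ld_triplets <- function(variants, config) {
  block <- ceiling(seq_len(nrow(variants)) / config$ld_block_size)
  rows <- list()
  for (b in unique(block)) {
    idx <- which(block == b)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    rows[[length(rows) + 1]] <- data.frame(
      rsid_a = variants$rsid[pairs[1, ]], rsid_b = variants$rsid[pairs[2, ]],
      r2 = config$ld_rho^2, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    data.frame(rsid_a = character(0), rsid_b = character(0), r2 = numeric(0))
  } else {
    do.call(rbind, rows)
  }
}

#' Simulate a paired exposure/outcome summary-statistics dataset
#'
#' Draws one exposure cohort and one outcome cohort from the generative model
#' in [sim_config()], sharing true per-SNP effects, and returns them in the
#' same standardized record format the readers produce, plus a block-LD
#' lookup. Fully reproducible from `config$seed`.
#'
#' @param config a `sim_config`.
#' @param exposure_id,outcome_id identifiers stamped on the records.
#' @return list with `exposure` and `outcome` (`summary_stats` objects), `ld`
#'   (lookup function), `ld_table` (long-format triplets) and `truth`
#'   (data frame of `rsid`, `maf`, `gamma_true`).
#' @export
simulate_pair <- function(config, exposure_id = "exposure",
                          outcome_id = "outcome") {
  stopifnot(inherits(config, "sim_config"))
  v <- .sim_variants(config)
  exposure <- .sim_exposure_obs(v, config, exposure_id)
  outcome <- .sim_outcome_obs(v, config, v$gamma_true)
  list(
    exposure = structure(list(role = "exposure", id = exposure_id,
                              records = exposure, rejects = NULL),
                         class = "summary_stats"),
    outcome = structure(list(role = "outcome", id = outcome_id,
                             records = outcome, rejects = NULL),
                        class = "summary_stats"),
    ld = .block_ld(v, config),
    ld_table = .ld_triplets(v, config),
    truth = v[, c("rsid", "maf", "gamma_true")]
  )
}

#' Write a simulated pair (or any record tables) to TSV files
#'
#' Writes `<prefix>_exposure.tsv`, `<prefix>_outcome.tsv` and `<prefix>_ld.tsv`
#' under `dir`, using the IEU-style header the default reader dialect expects.
#'
#' @param sim result of [simulate_pair()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of paths written, invisibly.
#' @export
write_simulated_pair <- function(sim, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_exposure.tsv", "_outcome.tsv",
                                           "_ld.tsv")))
  .write_records_tsv(sim$exposure$records, paths[1])
  .write_records_tsv(sim$outcome$records, paths[2])
  utils::write.table(sim$ld_table, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# Standardized records -> IEU-style TSV (SNP/chr/pos/... header).
.write_records_tsv <- function(rec, path) {
  out <- data.frame(SNP = rec$rsid, chr = rec$chrom, pos = rec$pos,
                    effect_allele = rec$ea, other_allele = rec$oa,
                    beta = rec$beta, se = rec$se, pval = rec$pvalue,
                    stringsAsFactors = FALSE)
  if (!is.null(rec$eaf)) out$eaf <- rec$eaf
  if (!is.null(rec$n)) out$n <- rec$n
  if (!is.null(rec$consequence)) out$consequence <- rec$consequence
  if (!is.null(rec$cis)) out$cis <- rec$cis
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a small multi-exposure dataset exercising every decision branch
#'
#' Emits a deterministic fixture of five exposures, two outcome GWAS datasets
#' and one independent validation cohort, constructed so the causal-call
#' pipeline visits every branch:
#' \describe{
#'   \item{mir-repl}{truly protective, instruments present in both cohorts —
#'     the replicated high-confidence call.}
#'   \item{mir-disc}{protective in discovery, but its validation instruments
#'     are exactly orthogonal to the outcome effects — replication fails.}
#'   \item{mir-null}{no causal effect (outcome residuals constructed as a tiny
#'     alternating pattern, so the null holds at every seed).}
#'   \item{mir-two}{only 2 SNPs — fails the minimum-instrument gate.}
#'   \item{mir-noval}{truly protective but absent from the validation cohort —
#'     replication unavailable.}
#' }
#' The second outcome dataset is a constructed negative control (near-zero
#' effects for every SNP). Branch-critical quantities are deterministic;
#' remaining draws are seeded.
#'
#' @param seed root seed.
#' @return list with `discovery` and `validation` (named lists of exposure
#'   record data frames), `outcomes` (named list of outcome record data
#'   frames), `ld` (lookup), and `truth` (per-exposure scaffolds).
#' @export
make_paper_like_fixture <- function(seed = 1) {
  specs <- list(
    `mir-repl` = list(J = 30L, beta = -0.20, chrom = "1", offset = 0L),
    `mir-disc` = list(J = 24L, beta = -0.15, chrom = "2", offset = 1000L),
    `mir-null` = list(J = 20L, beta = 0, chrom = "3", offset = 2000L),
    `mir-two`  = list(J = 2L,  beta = 0, chrom = "4", offset = 3000L),
    `mir-noval` = list(J = 30L, beta = -0.20, chrom = "5", offset = 4000L)
  )
  n_validation <- 710L

  discovery <- list()
  validation <- list()
  out1 <- list()
  out2 <- list()
  truth <- list()

  for (id in names(specs)) {
    sp <- specs[[id]]
    cfg <- sim_config(n_snps = sp$J, causal_beta = sp$beta,
                      seed = substream_seed(seed, id))
    v <- .sim_variants(cfg, chrom = sp$chrom, rsid_offset = sp$offset)
    truth[[id]] <- v
    discovery[[id]] <- .sim_exposure_obs(v, cfg, id)

    alt <- 0.1 * (-1)^seq_len(sp$J)  # tiny deterministic residual pattern
    deterministic_null <- id %in% c("mir-disc", "mir-null", "mir-two")
    out1[[id]] <- .sim_outcome_obs(
      v, cfg, discovery[[id]]$beta, stream = "Gamma_obs_1",
      residual = if (deterministic_null) alt else NULL)

    cfg2 <- cfg
    cfg2$causal_beta <- 0
    out2[[id]] <- .sim_outcome_obs(v, cfg2, v$gamma_true, residual = alt)

    if (id != "mir-noval") {
      se_v <- .se_exposure(v$maf, n_validation)
      if (id == "mir-disc") {
        # strong instruments exactly orthogonal (in IVW weights) to the
        # outcome-1 effects: the replication slope is identically zero
        w <- 1 / out1[[id]]$se^2
        s <- (-1)^seq_len(sp$J)
        t <- w * out1[[id]]$beta
        gv <- 0.4 * s - (0.4 * sum(s * t) / sum(t * t)) * t
      } else {
        gv <- .with_stream(cfg$seed, "gamma_obs_validation",
                           stats::rnorm(sp$J, 3 * v$gamma_true, se_v))
      }
      validation[[id]] <- data.frame(
        rsid = v$rsid, chrom = v$chrom, pos = v$pos, ea = v$ea, oa = v$oa,
        beta = gv, se = se_v, pvalue = mr_pvalue(gv, se_v),
        eaf = v$maf, n = n_validation,
        consequence = NA_character_, cis = NA,
        stringsAsFactors = FALSE
      )
    }
  }

  list(
    discovery = discovery,
    validation = validation,
    outcomes = list(
      bc_gwas_1 = do.call(rbind, c(out1, list(make.row.names = FALSE))),
      bc_gwas_2 = do.call(rbind, c(out2, list(make.row.names = FALSE)))
    ),
    ld = function(a, b) if (a == b) 1 else 0,
    truth = truth
  )
}

#' Write a multi-exposure fixture to TSV files
#'
#' One exposure TSV per cohort and exposure, one TSV per outcome dataset.
#' Byte-identical across runs for the same fixture.
#'
#' @param fixture result of [make_paper_like_fixture()].
#' @param dir output directory.
#' @return character vector of paths written, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(fixture$discovery)) {
    p <- file.path(dir, paste0("discovery_", id, ".tsv"))
    .write_records_tsv(fixture$discovery[[id]], p)
    paths <- c(paths, p)
  }
  for (id in names(fixture$validation)) {
    p <- file.path(dir, paste0("validation_", id, ".tsv"))
    .write_records_tsv(fixture$validation[[id]], p)
    paths <- c(paths, p)
  }
  for (id in names(fixture$outcomes)) {
    p <- file.path(dir, paste0("outcome_", id, ".tsv"))
    .write_records_tsv(fixture$outcomes[[id]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
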