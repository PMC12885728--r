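---
title: "Methods: two-sample MR of circulating miRNA exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of circulating miRNA exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Circulating microRNA levels are heritable, and cis-acting eQTLs provide
natural instruments for asking whether genetically elevated miRNA expression
changes disease risk. `mirmr` implements the two-sample summary-statistics
form of Mendelian randomization: for SNP $j$ we observe an estimated effect
$\hat\gamma_j$ (with standard error $\sigma_{\gamma j}$) on the miRNA from an
eQTL cohort, and an estimated effect $\hat\Gamma_j$ (with $\sigma_{\Gamma j}$,
log-odds scale) on the disease from an independent case-control GWAS. Under
the instrumental-variable assumptions each SNP supplies a Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ for the causal effect $\beta$.

The inverse-variance weighted (IVW) estimator pools these ratios as a
weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the origin with
weights $w_j = 1/\sigma_{\Gamma j}^2$:

$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\gamma_j \hat\Gamma_j}
                         {\sum_j w_j \hat\gamma_j^2}.$$

MR-Egger refits the same weighted regression with a free intercept after
orienting every $\hat\gamma_j \ge 0$ (jointly flipping the sign of each
$(\hat\gamma_j, \hat\Gamma_j)$ pair; without this orientation the intercept is
not identifiable under allele recoding). The intercept estimates the average
directional pleiotropic effect; under the InSIDE assumption (pleiotropy
independent of instrument strength) the slope remains a consistent estimate
of $\beta$ even when every instrument is pleiotropic.

## Estimator conventions

Several conventions are open in summary-data MR; the package fixes them as
follows and the worked examples in the test suite confirm that the published
numbers this package reproduces follow the same conventions.

* **IVW error model.** Default is multiplicative random effects: the
  fixed-effect standard error $\sqrt{1/\sum_j w_j\hat\gamma_j^2}$ is
  multiplied by the residual scale $\sqrt{Q/(J-1)}$ floored at 1, so
  heterogeneity can widen but never shrink the interval. IVW p-values use the
  normal reference (a published IVW row with beta $-0.00572$ and SE
  $0.00227$ recomputes to $p = 0.0117$ under the normal, matching print).
* **MR-Egger inference.** Coefficient standard errors are the unscaled WLS
  errors times the residual scale floored at 1; p-values use $t_{J-2}$
  (the published Egger row with beta $-0.01252$, SE $0.00817$, 23 SNPs gives
  $p = 0.1404$ under $t_{21}$, not under the normal).
* **Confidence intervals.** Wald intervals on the log-odds scale with the
  normal quantile at every $J$; odds ratios by exponentiation. Report
  rendering rounds beta/SE/p to 5 decimals and OR/CI to 3, trimming trailing
  zeros ("0.99", not "0.990").
* **Cochran Q** is computed about the fixed-effect IVW estimate,
  $Q=\sum_j w_j(\hat\Gamma_j-\hat\beta\hat\gamma_j)^2$, with an upper-tail
  $\chi^2_{J-1}$ p-value; at 2 df this reduces to $e^{-Q/2}$ exactly.
* **Leave-one-out** refits the headline IVW mode on each $J-1$ subset, in
  SNP order, flagging single-variant dominance.

## Harmonization and instrument selection

Exposure and outcome tables are matched by rsid (position disagreement at a
matching rsid is a warning, not a drop — genome builds differ across public
summary statistics). Swapped effect/other alleles negate the outcome beta and
are flagged; inconsistent allele sets are dropped as mismatches. All
palindromic SNPs (A/T, C/G) are dropped unconditionally — no allele-frequency
rescue, since strand-frequency inference is unreliable exactly where it
matters. Non-palindromic complement pairs (A/G vs T/C) are treated as
mismatches rather than complement-matched; with rsid-matched modern exports
these are rare, and silently complement-matching would mask data errors.
Duplicate rsids keep the smallest p-value. Output ordering is fixed to
(chrom, pos, rsid) so every downstream table is bit-reproducible.

Instrument selection applies, in order: a cis filter and a coding-consequence
exclusion (synonymous/missense, to limit pleiotropy through protein-altering
variation) when the annotations are present — validation-cohort exports
typically lack them and the filters are then skipped with a warning; a
Benjamini-Hochberg FDR over the surviving p-values at $q < 0.1$, computed
within one exposure's candidates (the conservative reading when each miRNA's
instruments are selected separately); and a strength filter $F > 10$ with
$F = (\hat\gamma/\sigma_\gamma)^2$. LD clumping is greedy by ascending
p-value: a record is pruned only when an already-kept record on the same
chromosome is *both* within the window *and* correlated at
$r^2 \ge$ threshold. The defaults ($r^2 < 0.5$, 10 kb) are deliberately
liberal — they reproduce an analysis style in which nearby, weakly
correlated eQTL signals are retained — and both knobs are exposed in the
configuration. LD is an input (matrix or triplet table; absent pairs default
to $r^2 = 0$); the package does not compute LD from genotype panels.

## Decision rules

A discovery call requires all four of: IVW $p < .05$; BH FDR $q < 0.1$
computed across all exposures fitted against that outcome (the only family
that makes the criterion non-vacuous when dozens of miRNAs are screened per
outcome); sign agreement between the IVW and Egger slope point estimates
(zero counts as disagreeing); and at least 3 SNPs in the fit. SNPs reaching
genome-wide significance for the outcome ($p \le 5\times10^{-8}$) are
excluded before fitting, so instruments are not themselves outcome loci.

Replication refits IVW with independently selected validation-cohort
instruments (relaxed $p < 10^{-5}$ selection, no annotation filters) against
the same outcome. By default replication requires the discovery direction in
addition to $p < .05$; a significant wrong-signed validation estimate should
not count as support, though the requirement is switchable for
sensitivity analyses. Exposures absent from the validation cohort are
reported as replication-unavailable, and only discovery-passing,
replication-passing calls are flagged high confidence. Diagnostics
(Q, Egger intercept, leave-one-out) are reported, never acted on
automatically.

## The synthetic generator

`sim_config()`/`simulate_pair()` emulate the statistical structure the
pipeline consumes: MAFs uniform on a range; true instrument effects
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma^2)$; exposure standard errors from
the standardized-trait approximation $1/\sqrt{2n\,\mathrm{MAF}(1-\mathrm{MAF})}$;
outcome standard errors from the case-control approximation
$\sqrt{(1/n_{cases}+1/n_{controls})/(2\,\mathrm{MAF}(1-\mathrm{MAF}))}$;
pleiotropy $\alpha_j = \mu_\alpha + \tau Z_j$, optionally correlated with
$\gamma_j$ to break InSIDE; observed effects are truths plus Gaussian noise
at those standard errors. These formulas are internally consistent rather
than cohort-exact, which is all the calibration studies require. Defaults
mirror the study conditions: 35,102 cases / 388,356 controls for the outcome
GWAS, an eQTL discovery cohort of 5000, a validation cohort of 710. LD is
block-constant (compound symmetry within blocks), the simplest structure
that makes clumping non-trivial. All draws flow from one root seed through
named substreams (`substream_seed()`), so adding a draw to one group never
perturbs another.

What the generator does **not** emulate: realistic allele-frequency spectra,
LD decay with distance, winner's-curse selection of instruments, sample
overlap between cohorts, or miRNA effect-size distributions. Passing
calibration therefore demonstrates internal statistical correctness of the
estimators and decision logic, not robustness to those real-data
complications.

## Calibration study sizes and results

The calibration suite (also run by `scripts/acceptance.R` and
`analysis/04_calibration.R`) uses sizes chosen to pin the Monte-Carlo error
well inside the acceptance bands while running in seconds: 1000 replicates
for the type-I study (null model, $J=30$), 500 for causal-effect recovery
($\beta=-0.3$, $J=50$) and 500 for pleiotropy recovery ($\mu_\alpha=0.02$,
$\tau=0$, $J=100$). The recovery studies use an exposure cohort of 20,000 —
"strong instruments" — because with observed (noisy) $\hat\gamma$ in the
denominator all ratio estimators carry regression-dilution bias of order
$\sigma_{\gamma}^2/E[\gamma^2]$; at $n=5000$ that is a visible ~5%
attenuation of $\beta$, at 20,000 it is well under 1%. The same mechanism
leaks a few thousandths into the Egger intercept, which is why its recovery
sits near 0.017–0.018 for a true 0.02: a property of noisy-instrument MR, not
an implementation artifact. The random-effects IVW with the floored residual
scale rejects slightly below nominal under the null (~4–5%), as the floor is
one-sided.

## The decision fixture

`make_paper_like_fixture()` builds a five-exposure dataset that drives the
decision pipeline through every branch: a replicated protective miRNA, a
discovery-only miRNA, a constructed null, a two-SNP exposure that fails the
minimum-instrument gate, and a protective miRNA absent from validation.
Because a decision-branch fixture must land in the same branches at *any*
seed, the branch-critical quantities are constructed rather than drawn: the
null exposure's and the negative-control outcome's residuals are a tiny
alternating pattern ($0.1\sigma_\Gamma$, so the IVW z-statistic is bounded
near zero), and the discovery-only exposure's validation instruments are
exactly orthogonalized (in IVW weights) against the outcome effects, making
its replication slope identically zero. Effect sizes (−0.20, −0.15) are set
so that per-SNP outcome associations stay clear of the genome-wide
significance exclusion while the pooled IVW is decisive. Everything else
(MAFs, alleles, instrument effects, noise for the two truly causal
exposures) is seeded-random.

## Degenerate inputs and numerical choices

Zero exposure effects make the Wald ratio undefined: `wald_ratios()` errors
naming the SNP. Estimators enforce their minimum SNP counts ($J\ge1$ fixed
IVW, $\ge2$ random-effects, $\ge3$ Egger and leave-one-out) with explicit
errors; harmonization returning zero SNPs is a warning, and the pipeline
reports such exposures as gate failures rather than aborting the run.
Tie-breaks are lexicographic on (p-value, chrom, pos, rsid) everywhere a
scan order matters. p-values are reported untruncated; the BH adjustment
delegates to `stats::p.adjust` and is cross-checked against a brute-force
tail-cummin oracle in the tests.

## Known limitations

No weighted-median, mode-based, MR-PRESSO or Steiger estimators; no
multivariable MR; no proxy-SNP search for instruments missing in the
outcome; no strand inference from allele frequency; no liftover; no LD
computation from reference panels; no network access — all inputs are local
delimited text files.
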