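---
title: "Methods: bidirectional two-sample MR for microbiome exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR for microbiome exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflora)
```

## The inference problem

mrflora estimates the causal effect of gut-microbiota taxon abundances on a
binary pregnancy outcome (hyperemesis gravidarum, HG) — and the reverse —
from GWAS summary statistics alone. Individual-level data are never needed:
each analysis consumes one table of per-SNP associations with the exposure
(a taxon abundance from a microbiome GWAS meta-analysis of roughly 18,340
participants and 211 taxa spanning genus to phylum ranks) and one with the
outcome (a case–control GWAS on the log-odds scale, roughly 1,148 cases and
110,330 controls).

A genetic variant is a valid instrument under the three classical IV
assumptions: it is (1) robustly associated with the exposure (relevance),
(2) independent of exposure–outcome confounders (independence), and (3)
affects the outcome only through the exposure (exclusion restriction).
Relevance is enforced and quantified by the instrument-selection module;
the other two are unverifiable and are probed by the sensitivity suite.

## Instrument selection and quality control

Instruments pass through four filters, each recorded in a provenance table
(`iv_provenance()`), so `input = retained + dropped` holds at every stage:

1. **P-value threshold.** Genome-wide significance `p < 5e-8` (strict
   inequality; ties at the cutoff are excluded). Microbiome GWAS rarely
   yield enough genome-wide hits per taxon, so when fewer than
   `min_instruments` (default 3) survive, the pipeline falls back to the
   locus-wide threshold `1e-5` and flags the run. The minimum of 3 is our
   choice: it is the smallest count at which MR-Egger, the weighted median
   and the mode estimators are defined, so a fallback below it would leave
   the analysis without its supplementary estimators.
2. **Greedy LD clumping.** Candidates are ranked by ascending p-value, ties
   broken by chromosome, position, then identifier so output is fully
   deterministic. The best remaining SNP is kept and every remaining SNP on
   the same chromosome within the window (default 10,000 kb, inclusive:
   `|Δpos| ≤ window`) with `r² ≥ r2_max` is discarded. The forward analysis
   uses `r2_max = 0.001`, the reverse `0.1`. Candidates absent from the LD
   matrix are treated as independent with a warning — a complete panel
   matrix exists on the synthetic path, but a user-supplied matrix may be
   partial.
3. **Palindrome removal.** A/T and C/G SNPs are removed unconditionally.
   No frequency-based strand rescue is attempted: with an ambiguous strand,
   allele frequencies near 0.5 cannot arbitrate, and the removal rule keeps
   the harmonization step free of strand inference entirely.
4. **Harmonization.** Outcome effects are aligned to the exposure's effect
   allele: identical pairs pass through, swapped pairs flip the outcome
   beta and reflect its frequency, irreconcilable pairs are dropped. The
   step is idempotent, and the whole analysis is invariant to a global
   allele recoding of the outcome file (both properties are tested).

Instrument strength uses the variance explained per SNP,

$$R^2_j = \frac{2\beta_j^2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)}
{2\beta_j^2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j) +
 2\,\mathrm{SE}_j^2\,N\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)},$$

and the F-statistic over the K retained SNPs,

$$F = \frac{N-K-1}{K}\cdot\frac{R^2}{1-R^2},$$

with F > 10 the conventional bar below which weak-instrument bias is a
concern. Because it is ambiguous whether the published convention applies
the F formula per SNP or cumulatively, `instrument_strength()` reports
both (`f_min` with K = 1 per SNP, and the cumulative `f_stat`), and the
weak-instrument flag is raised if either fails the bar. When per-SNP sample
sizes differ, F uses the minimum — the conservative choice.

## The five estimators

All methods are built on per-SNP Wald ratios
$\hat\theta_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$ with first-order standard
errors $\mathrm{SE}_{Y,j}/|\hat\beta_{X,j}|$ (second-order available by
flag; the first-order form is the common default and matches the
inverse-variance weights used by the regression formulations).

- **IVW** (primary): weighted regression of outcome on exposure effects
  through the origin, weights $1/\mathrm{SE}_Y^2$. The default is
  multiplicative random effects — the fixed-effects standard error scaled
  by $\max(1, \sqrt{Q/(K-1)})$ — which reduces to fixed effects under
  homogeneity and never understates uncertainty; fixed effects are
  available via `mode = "fixed"`. P-values are normal.
- **MR-Egger**: the same regression with an intercept after orienting all
  exposure effects non-negative. The slope is the pleiotropy-adjusted
  estimate; the intercept estimates average directional pleiotropy.
  Standard errors use the residual scale floored at 1, p-values from
  t(K − 2). On an exactly collinear fit the residual scale is numerically
  zero (detected at `sigma < 1e-8`); standard errors are then reported as
  zero with p-values of 0 (or 1 for a parameter estimated exactly zero,
  detected at `|estimate| < 1e-10`).
- **Weighted median**: ratios ordered, cumulative normalized
  inverse-variance weights, linear interpolation at cumulative weight 0.5;
  consistent when at least half the weight is valid. Standard error by
  parametric bootstrap: ratios resampled from
  $N(\hat\theta_j, \mathrm{SE}(\hat\theta_j))$ with weights held fixed,
  default 1000 replicates, seeded.
- **Weighted and simple mode**: the argmax of a weighted normal-kernel
  density of the ratios, bandwidth
  $h = \phi \times 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)K^{-1/5}$
  (default $\phi = 1$), evaluated on a 512-point grid spanning the ratios
  plus three bandwidths. Argmax ties are broken toward the weighted mean of
  the ratios, so degenerate inputs are deterministic. If the IQR collapses
  to zero while the spread does not, the sd-based bandwidth is used; if all
  ratios coincide, the estimate is that common value with zero standard
  error. Bootstrap standard errors as for the median; the bandwidth is
  recomputed inside each bootstrap replicate.

`run_all_methods()` dispatches on K: one SNP yields only the Wald ratio;
two yield IVW plus a Wald-type estimate; three or more yield all five.
The "wald" method is defined here as the inverse-variance-weighted mean of
the per-SNP Wald ratios, which reduces to the classic single-SNP Wald
ratio at K = 1 — a deliberate generalization so that the K = 2 case still
reports two estimates even though the regression-with-intercept methods
are undefined there. Odds ratios are `exp(beta)` with 95% intervals using
1.96 exactly.

## Sensitivity suite

- **Cochran's Q** (K ≥ 2): $Q=\sum_j w_j(\hat\theta_j-\hat\beta)^2$ against
  chi-square(K − 1); with first-order weights this is algebraically the
  weighted residual sum of squares of the IVW fit. Heterogeneity is
  declared at p < 0.05, with no multiplicity correction anywhere in the
  sensitivity suite — each diagnostic answers its own question about one
  instrument set, and correcting across the exposure panel would change
  the per-taxon operating characteristics the thresholds were chosen for.
- **Egger intercept test** (K ≥ 3): two-sided t(K − 2) test of the
  intercept against zero; directional pleiotropy at p < 0.05.
- **Leave-one-out** (K ≥ 3): K IVW refits omitting each SNP plus the full
  fit (K + 1 rows); a `driver` flag marks omissions that flip the sign of
  the estimate or move its p-value across 0.05.
- **MR-PRESSO** (K ≥ 4): residual sum of squares with leave-one-out IVW
  predictions, a parametric simulation for the global test (pseudo-count
  `+1` in `(1 + #{RSS* ≥ RSS})/(n_sim + 1)` keeps p-values off zero),
  per-SNP outlier p-values from each SNP's simulated residual
  distribution with Bonferroni correction across the K instruments
  (default familywise level 0.05), and a distortion test comparing the
  outlier-removal shift against removals of random instrument subsets of
  the same size. Default `n_sim = 1000`. By default MR-PRESSO runs only in
  the reverse direction, mirroring the headline analysis design; a
  `presso_directions` flag enables it everywhere.

All stochastic components (bootstraps, MR-PRESSO) accept a seed and are
exactly reproducible given `(seed, n_sim)`; the pipeline derives per-taxon
seeds deterministically from the master seed, so identical configuration
yields byte-identical report directories (the run-metadata file records
thresholds and seeds and deliberately no timestamps).

## The synthetic-data generator

`simulate_mr_dataset()` emulates the study's data shapes directly on the
summary-statistic scale rather than simulating genotypes: per-SNP exposure
effects $\gamma_j$ are drawn from a configurable magnitude range with mixed
or positive signs; exposure estimates are
$\hat\beta_{X,j}\sim N(\gamma_j, \mathrm{SE}_{X,j})$ with the analytic
standard error $\mathrm{SE}_{X,j}=1/\sqrt{2\,\mathrm{maf}_j
(1-\mathrm{maf}_j)N}$ at the default exposure size N = 18,340; outcome
estimates are $\hat\beta_{Y,j}\sim N(\beta\gamma_j+\alpha_j,
\mathrm{SE}_{Y,j})$ where $\beta$ is the causal effect, $\alpha_j$ the
per-SNP pleiotropy (none, balanced, or directional), and
$\mathrm{SE}_{Y,j}$ uses the binary-trait effective sample size
$N_\mathrm{eff}=4/(1/N_\mathrm{cases}+1/N_\mathrm{controls})$ at the
default 1,148 / 110,330. Wald p-values are clamped at `1e-300` so that an
extremely strong association never underflows to an invalid p of exactly
zero. Block LD is available as an AR-decay r² structure
($r^2=\rho^{2|i-j|}$ within a block, blocks placed within the clumping
window, distinct blocks outside it).

The default effect-magnitude range (|γ| uniform on [0.04, 0.08]) gives
per-SNP variance explained around 0.1–0.15%, summing to roughly 1–3%
across panels of 10–30 instruments with per-SNP F comfortably above 10 —
the strong-but-realistic regime a microbiome GWAS instrument set occupies.

`simulate_taxa_panel()` builds a reduced-scale multi-taxon panel: each
taxon has an independent instrument set (taxa are treated as separate
exposures, with no cross-taxon genetic correlation), names cycle through
the five taxonomic rank prefixes and include an `unknowngenus`
placeholder, a chosen number of taxa carry causal effects with alternating
signs, and the shared outcome additionally carries direct susceptibility
loci with no effect on any taxon — these are what make the reverse
direction testable, since a binary outcome's instruments must come from
its own GWAS. Exposure and outcome tables cover the union of panel SNPs,
as they would in genotyped cohorts.

What the generator does *not* emulate: genotype-level LD beyond the block
r² structure, allele-frequency differences between cohorts, sample overlap
between exposure and outcome GWAS, winner's-curse selection of published
instruments, and the compositional correlation structure of real taxon
abundances. Tests passing on synthetic data therefore establish the
correctness and calibration of the estimators and pipeline logic under the
stated generative model — not robustness to those real-data complications.

## Validation design and problem sizes

The statistical test suite checks, at fixed seeds chosen in advance:
exact agreement of IVW and Egger with closed-form weighted least-squares
oracles (200 random instances, 1e-10 relative); agreement of the clumping
algorithm with a brute-force re-implementation on 500 randomized small
instances including p-value ties; formula audits of R² and F on 1000
random inputs at 1e-12; IVW type-I error within [0.035, 0.065] and
parameter recovery with 93–97% interval coverage at K = 30 instruments
over 2000 replicates; the pleiotropy contrast (Egger slope nearly
unbiased, IVW visibly biased, intercept recovering the pleiotropy mean)
over 1000 replicates; chi-square calibration of Q over 5000 draws;
MR-PRESSO detection of a planted 10-SE outlier over 200 replicates; and 50
end-to-end panel replicates (20 taxa, 2 causal at |log-odds| 0.5, 15 SNPs
per taxon) checking recovery, reverse gating and reverse-null calibration.
Panel replicates use 50 bootstrap draws and 150 MR-PRESSO simulations per
run; these sizes keep the whole suite to a few minutes while leaving
Monte-Carlo error far smaller than the tested margins.

Two generator regimes appear in those checks. The calibration and
recovery checks use the default strong-but-realistic instruments
(|γ| ∈ [0.05, 0.1]). The pleiotropy contrast instead uses very strong,
positively oriented instruments (|γ| ∈ [0.15, 0.8]): MR-Egger is
consistent only as exposure-effect measurement error vanishes (the NOME
condition), and its slope and intercept are otherwise attenuated by
regression dilution. Isolating the pleiotropy behaviour from that known,
separate phenomenon requires making dilution negligible; positive
orientation is needed because with mixed-sign effects the orientation step
flips pleiotropy signs in tandem and the directional-pleiotropy bias of
IVW averages toward zero.

## Known limitations

- First-order Wald weights ignore exposure-side sampling error (NOME); at
  realistic microbiome instrument strength this attenuates all estimators
  by a few percent, visible in the recovery checks as a mean estimate a
  shade below truth but well inside coverage bounds.
- The weighted-median and mode standard errors are parametric bootstraps
  under independent normal ratios; they inherit that approximation.
- MR-PRESSO's distortion test requires at least two non-outlying
  instruments and is reported as `NA` otherwise.
- No multivariable MR, MR-RAPS, contamination mixture, Radial-MR, Steiger
  filtering or I² statistics: the package implements exactly the five
  estimators and four diagnostics of the study design it reproduces.
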