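---
title: "Methods: stress-associated DMR detection, classification and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stress-associated DMR detection, classification and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresswgbs)
```

## Scope and data model

The package implements the computational chain of a perinatal
epigenomics study design: whole-genome bisulfite sequencing (WGBS) of two
small exposure groups (children or mothers with low vs high perceived
prenatal stress), region-level differential methylation analysis,
classification of regions by genetic influence, annotation enrichment, and
the subject-level epidemiology of a birth cohort (stress questionnaire,
wheeze outcome, biomarkers).

Coordinates follow the two community conventions simultaneously: CpG and
SNP positions are 1-based (VCF), all intervals are 0-based half-open
(BED). `pos_to_interval()` / `interval_to_pos()` own the conversion; no
other code does +/- 1 arithmetic. Strand is ignored throughout — CpG
methylation is treated as strand-collapsed.

## Smoothing

WGBS coverage per CpG is low (here ~15x), so raw per-CpG proportions are
noisy. Each sample's profile is smoothed with a local-likelihood-style
estimator: at every CpG a weighted least-squares quadratic in position is
fitted to the count proportions, weights `total * tricube(d/h)`, over the
smallest symmetric window that spans at least `min_window_bp` and contains
at least `min_window_cpgs` CpGs. The fitted value at the CpG, clipped to
[0, 1], is the smoothed methylation.

Defaults (2 kb, 70 CpGs) suit genome-scale human data, where CpG density
is an order of magnitude higher than on the package's simulated grids.
**Bandwidth guidance:** the window should be on the scale of the regions
you want to resolve. On the default simulated genome (mean CpG spacing
100 bp, target regions of 5–10 CpGs, i.e. roughly 0.4–0.9 kb) the package's
tests and acceptance script use `smooth_params(1200, 13)` — a window about
the size of the largest target region. A 70-CpG window on that grid spans
~7 kb and averages any region-scale signal below the calling threshold
regardless of effect size; conversely, windows much narrower than the
target region sacrifice the noise averaging that the low per-CpG coverage
requires. This bandwidth is a tuning parameter of the estimator and is
deliberately not baked into the generator or the thresholds.

Degenerate cases: a window whose CpGs have fewer than three distinct
covered positions falls back to a weighted mean; a chromosome with zero
coverage everywhere is an error naming the chromosome.

## The floored t statistic and region calling

At each CpG the group difference of smoothed values,
`d = mean(high) - mean(low)`, is divided by a pooled equal-variance
two-sample standard error. Because smoothing makes some standard errors
spuriously tiny, raw standard errors are floored at their genome-wide 75th
percentile before division (`floor_quantile`, configurable). With 5
samples per group the raw variance estimate has 8 df and the floor is what
keeps single-CpG flukes from dominating.

Regions are maximal runs of adjacent CpGs with `|t| > 4.5`, constant sign,
and neighboring member CpGs at most `max_gap_bp = 300` apart, kept when
they have >= 3 CpGs and `|mean(d)| > 0.10`. "Adjacent" means consecutive
on the CpG grid: a single failing CpG inside a stretch splits it. The gap
rule makes "consecutive CpGs" operational on grids with variable spacing;
300 bp is three times the simulated mean gap and is exposed in
`dmr_call_params()`. Region bounds span first to last member CpG,
half-open; `direction` is hyper when the high-exposure group is more
methylated. An exhaustive run-enumeration oracle in the test suite pins
this scan exactly on small fixtures.

## Permutation FDR

The false discovery rate of a calling configuration is estimated by
re-running the statistic and the scan under balanced permutations of the
group labels (per-sample smoothing does not depend on labels and is
reused). For equal groups a relabeling and its complement produce
identical calls up to sign and count once; 5-vs-5 gives
`choose(10, 5) / 2 - 1 = 125` distinct non-identity relabelings,
enumerated exhaustively when `n_perms` exceeds that. FDR = mean null
count / observed count, reported as 1 when nothing was observed. With the
variance floor recomputed per permutation, the null calls are exchangeable
with the observed ones.

## meQTL classification (gDMR / ngDMR)

For each region, per-sample regional methylation is the coverage-weighted
raw mean `sum(M)/sum(N)` over member CpGs — raw, not smoothed, so genotype
effects cannot leak across the region boundary through the smoother. Every
SNP within +/- 5 kb (boundary inclusive) is tested by Pearson correlation
against regional methylation, two-sided p from the t distribution with
n - 2 df. One significant SNP at alpha = 0.05 makes the region a gDMR;
otherwise it is an ngDMR, and untestable neighborhoods (no SNP, constant
dosage, < 3 complete pairs) default to ngDMR, so the two labels partition
the input. No multiple-testing correction is applied per default: the
classification deliberately over-calls gDMRs, which is the conservative
direction when the scientific interest lies in the non-genetic fraction.
A BH-adjusted mode and an exact-permutation test (all n! orders, for the
small sample sizes where t-distribution p-values are fragile) are
available in `meqtl_params()`.

## Annotation enrichment

The overlap statistic is the number of regions hitting a track by >= 1 bp
(each region counted once), which depends only on covered bases. The null
repositions every region uniformly at random on its own chromosome,
length-preserving, placements independent and allowed to overlap each
other — the simplest null consistent with "randomly shuffled regions". An
optional exclusion mask triggers redraws. `z = (obs - mean)/sd` over the
shuffle distribution; the empirical p uses the add-one estimator so it is
never zero; a degenerate null (sd = 0, e.g. saturated or empty tracks) is
flagged rather than producing an infinite z. Within-chromosome shuffling
is the default because chromosome-scale composition differences would
otherwise masquerade as enrichment; genome-wide placement is available.

Array-overlap reporting (`array_overlap()`) counts regions containing at
least one cataloged CpG position — the quantity that says how much of the
signal a fixed array would have seen. Gene assignment is gene-body overlap
with a configurable flank (default 0 bp, since regional signals in this
design are predominantly intragenic); gene-set enrichment is the one-sided
hypergeometric tail with BH adjustment across sets, with gene sets read
from standard GMT files.

## Cohort statistics

The perceived-stress questionnaire has 20 items scored 1–4. The total
score is implemented as the **mean** item score: the reference study
design reports score summaries on a 1–4 scale (median 1.85, max 3.55),
which is consistent only with a per-item scale; a summed total would
differ by the constant factor 20 and would not change quartile membership.
Quartile cutpoints use linear interpolation between order statistics
(`type = 7`; nearest-rank available); scores strictly below Q1 are low,
strictly above Q3 high, ties at a cutpoint medium. Category sizes
therefore need not be n/4.

Odds ratios come in two numerically linked forms: the 2x2 contingency
`(a d)/(b c)` with Wald 95% interval, and `exp(coef)` from maximum-
likelihood logistic regression with confounders, which reproduces the
contingency estimate exactly when no covariates are supplied. Wald
intervals are used everywhere for determinism; other interval methods
differ in the second decimal, so interval bounds should not be treated as
exact reference values. Zero cells raise an error pointing to the optional
0.5 continuity correction rather than silently correcting.

Geometric-mean ratios for positive outcomes (methylation fractions,
expression, biomarkers) are `exp` of the exposure coefficient from OLS on
the log outcome — invariant to multiplicative rescaling of the outcome and
to affine rescaling of continuous covariates. Sub-cohort
representativeness uses the Pearson chi-square (no continuity correction)
on the category-by-cohort table.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
chain assumes, with every planted effect recoverable downstream:

* **CpG grid**: geometric gaps, mean 100 bp (no spacing model is implied
  by the design being emulated; geometric is the simplest renewal model).
* **Baseline methylation**: a random walk squashed into (0.2, 0.8) —
  smooth along the chromosome, bounded away from 0/1 so planted shifts of
  +/- 0.15 do not clip. `pi_range = c(1, 1)` gives the degenerate
  all-methylated boundary case.
* **Counts**: coverage truncated-Poisson (>= 1) with mean 15; methylated
  counts beta-binomial with dispersion rho = 0.02, a typical replicate
  overdispersion for WGBS; rho = 0 gives pure binomial.
* **Planted DMRs**: 50 disjoint runs of 5–10 CpGs, group shift
  +/- delta/2 with randomized sign (so hyper/hypo counts are balanced
  under the null of that comparison), delta = 0.3 by default.
* **meQTLs**: one cis SNP within +/- 5 kb of a chosen region; its dosage
  shifts the carrier's methylation inside the region by `beta_meqtl` per
  allele, centered at the heterozygote so the slope is exactly beta while
  typical regions stay inside [0, 1]. Background SNPs at ~1 per 10 kb give
  a cis window of about two SNPs. Counts at affected CpGs are redrawn, so
  the genotype step returns the superseding methylation table.
* **Cohort**: items load on a latent per-subject stress level and are
  thresholded to match a realistic marginal distribution (mean item score
  ~1.8); wheeze follows a logistic model with planted category odds
  ratios (defaults 2.44 / 1.39 on a 9.1% baseline) and optional covariate
  terms; the biomarker is log-normal with a planted high-vs-low
  geometric-mean ratio (default 1.5).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: sequence-dependent CpG density (CpG
islands), bisulfite conversion error, read-level artifacts and mapping
bias, linkage disequilibrium among SNPs, cell-composition heterogeneity,
and confounding structure beyond simple planted covariates. Results on
real WGBS data additionally depend on alignment and methylation calling,
which are out of scope.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run these experiments (sizes
chosen so the full suite completes in minutes on one CPU):

* **DMR recovery**: 5-vs-5 at 15x, delta = 0.3, 50 planted regions on a
  200 kb genome; sensitivity and precision (>= 1 bp overlap) against the
  truth set, averaged over three simulated datasets in the acceptance
  script. Bandwidth `smooth_params(1200, 13)` per the guidance above;
  thresholds t = 4.5, >= 3 CpGs, delta > 10%.
* **FDR self-consistency**: with delta = 0 the estimate is ~1 (observed
  and null counts agree — typically both zero at these thresholds); with
  delta = 0.4 the estimate is far below 0.1.
* **meQTL classification**: recovery is measured on the genetic channel in
  isolation (regions simulated without a group shift, beta = 0.25,
  maf = 0.3, n = 10). With a group shift of 0.3 superimposed, the
  group-term variance is of the same order as the genetic signal and a
  plain correlation at n = 10 has only ~60–70% power — that experiment
  would measure the group effect, not the classifier. The null experiment
  (beta = 0) bounds the false-gDMR rate by the per-SNP alpha times the
  ~2-SNP window budget.
* **Enrichment**: on a 3-region/2-interval toy genome of 100 bp the
  shuffle null's mean and sd are compared against exact enumeration of
  all placements; on simulated tracks, 80% placement near regions clears
  the standard-normal 5% upper tail and uniform tracks stay below it.
* **Estimator recoveries**: planted OR 2.44 at n = 50,000 subjects and
  planted MR 1.5 at n = 5,000, with log-scale replicate averaging (5
  replicates) so Monte-Carlo error is well inside the comparison
  tolerance; at these n a single replicate's sampling error is of the
  same order as a +/- 0.1 band on the OR.

Numerical choices worth knowing: smoothed values and simulated
probabilities are clipped to [0, 1]; the tricube halfwidth is inflated by
1e-9 so the boundary CpG keeps (negligible but defined) weight; quantiles
are type 7 unless configured otherwise; `derive_seed()` folds a stream
label into the global seed (djb2 hash mod 2^31 - 1) so stages are
independently reproducible; empirical p-values use add-one estimators and
cannot be zero.

## Known limitations

Pearson p-values at n = 10 are fragile (the exact-permutation option
exists for this reason); the FDR convention (1.0 when nothing is
observed) makes the null estimate non-informative rather than
conservative; the shuffle null ignores chromatin-scale clustering of
annotations, which can make z slightly anti-conservative on real tracks;
and the logistic layer does not model longitudinal wheeze phenotype
derivation — the four-level phenotype is consumed as a label, with only
its binary persistent form analyzed.
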