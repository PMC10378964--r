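---
title: "Methods: a case-control GWAS pipeline for spastic syndrome in pedigreed cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a case-control GWAS pipeline for spastic syndrome in pedigreed cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spastigen implements the genomic analysis of a binary, late-onset disease
(spastic syndrome) in pedigreed dairy cattle as one tested pipeline:
heritability of the liability, a kinship-aware single-SNP association scan
with chromosome-wise positive-FDR control, a bespoke post-GWAS filter
cascade, a replicated random-forest consensus scan, and LD/haplotype-block
and SNP-to-gene analyses. Because real cohorts of this kind are private,
the package ships a synthetic-cohort generator with the statistical
structure the analysis assumes, and every stage is validated on it.

## The liability-threshold model and the heritability stages

Disease status is modelled as the indicator that a latent, normally
distributed liability exceeds a threshold fixed by the prevalence
$\alpha$. Heritability on the two scales is linked by

$$h^2_o = h^2_u \frac{w^2}{\alpha(1-\alpha)}, \qquad
  w = \frac{e^{-z^2/2}}{\sqrt{2\pi}},\; z = \Phi^{-1}(1-\alpha),$$

implemented in `underlying_to_observed()` and its algebraic inverse
`observed_to_underlying()`. Only $z^2$ enters, so the sign convention for
the threshold is immaterial; the factor is maximal at $\alpha = 0.5$
(where it equals $2/\pi$) and symmetric in $\alpha \leftrightarrow
1-\alpha$.

`estimate_h2_pql_probit()` fits the threshold animal model
$P(y_i = 1) = \Phi(\mu + u_i)$, $u \sim N(0, A\sigma^2_u)$, by penalized
quasi-likelihood: probit working response and weights, then REML of the
working linear mixed model with the liability residual variance fixed
at 1. Because a single variance parameter remains free, the inner REML
step is a one-dimensional profile maximization of the REML log-likelihood
of $V = W^{-1} + \sigma^2_u A$ (golden-section search to $10^{-7}$),
which is simpler and at least as exact as average-information updates
with an EM fallback. Sparse relationship matrices go through CHOLMOD, so
block-structured half-sib cohorts of a few thousand animals fit in
milliseconds per evaluation.

**PQL attenuation.** With one binary record per animal, the PQL fixed
point underestimates $\sigma^2_u$ severely: in the package's own
simulation (100 paternal half-sib families of 20 offspring, prevalence
0.5, true $h^2_u = 0.4$, 20 replicates) the median PQL estimate is about
0.14. This is a property of the estimator, not of the data: the same
machinery applied to the equivalent sire-intercept model reproduces
`MASS::glmmPQL` to three decimals and recovers $h^2 \approx 0.44$ through
the sire-variance route, and the classical two-step estimator
`estimate_h2_binary_lmm()` — ordinary linear REML on the 0/1 phenotype
followed by the inverse scale transformation — recovers a median of about
0.37 on the same replicates. The two-step estimator is therefore the
recommended cross-check whenever absolute calibration of the
underlying-scale estimate matters; the PQL estimator is retained as the
pipeline's threshold-model fit and its attenuation is documented rather
than patched.

## The GQLS association scan

For each SNP the allelic proportion $y \in \{0, \tfrac12, 1\}$ (half the
counted-allele dosage) is the response and the 0/1 status $x$ the
covariate. The test is a quasi-score test of "allele frequency does not
depend on status" with a fixed, documented convention:

* working covariance $V = v(\mu_0) K$ with variance function
  $v(\mu) = \mu(1-\mu)/2$ (binomial in two alleles on the proportion
  scale) and $K$ the kinship correlation (pedigree $A$-submatrix by
  default, genomic relationship optionally);
* GLS null mean $\mu_0 = (1'K^{-1}y)/(1'K^{-1}1)$;
* score $U = x'V^{-1}(y - \mu_0)$, null variance
  $x'V^{-1}x - (x'V^{-1}1)^2/(1'V^{-1}1)$, and
  $T = U^2/\mathrm{Var}(U) \sim \chi^2_1$ under the null.

$T$ is invariant to the scale of $v$ and to allele relabeling, and with
$K = I$ reduces to the classic score test of a logistic-type mean model.
Monomorphic SNPs are flagged with $p = 1$ by convention. Missing
genotypes are dropped pairwise per SNP; for complete SNPs the $K$
factorization is computed once per cohort. No overdispersion parameter is
fitted by default; `estimate_dispersion = TRUE` divides all statistics by
the mean of $T$ over polymorphic SNPs (a moment estimator), for cohorts
where residual inflation is suspected.

Chromosome-wise multiplicity control uses Storey-style q-values computed
independently per chromosome (`chromosome_pfdr()`): $\hat\pi_0$ by the
smoother method over $\lambda \in \{0.05, \dots, 0.95\}$
(`smooth.spline`, 3 df, evaluated at $\lambda = 0.95$), with a fallback
$\hat\pi_0 = 1$ for chromosomes with fewer than 100 SNPs — where the
q-values coincide exactly with Benjamini–Hochberg adjusted p-values.
Tiers at 1/5/10% pFDR annotate each SNP. Manhattan exports truncate
$-\log_{10} q$ at 6 and flag exceedances.

## The post-GWAS cascade

SNPs significant at chromosome-wise pFDR ≤ 10% pass through three
cumulative screens, in fixed order, with per-stage survivor counts
reported overall and per chromosome:

1. **MAF ≥ 0.2** — with case prevalence near 60%, disease-contributing
   alleles are expected to be common;
2. **genotype chi-square, p < 0.05** — Pearson test on the 2 × k table
   of status by observed genotype class, no continuity correction, no
   expected-count minimum (a warning is logged for small tables);
3. **homozygotic polarity score ≥ 0.3** — within each phenotype class
   the proportions of the two homozygous genotypes are taken over all
   non-missing animals of the class, $d = p_{hom0} - p_{hom2}$, and the
   score is $|d_{case} - d_{control}| \in [0, 2]$. Large values mean the
   two homozygous states are enriched in opposite disease classes. When
   one homozygote is absent from the whole cohort there is only one
   homozygotic state and the score is undefined (N/A); N/A never passes
   the stage but the SNP stays in the report. Homozygote proportions use
   all animals of the class in the denominator (including heterozygotes);
   the alternative denominator (homozygotes only) would make the N/A case
   meaningless.

## The replicated random-forest consensus

`run_forest()` grows one classification forest (75 trees by default) on
the dosage features. "Even weighting of the prediction error between
disease statuses" is implemented as a balanced bootstrap
(inverse-class-frequency case weights, so each tree's in-bag sample is
approximately class-balanced) plus matching class weights in the split
criterion. VIM% is raw permutation importance (mean decrease in
out-of-bag accuracy) × 100; negative importances are recorded but count
as zero for retention decisions. Out-of-bag error is reported overall and
per class. A fixed seed and single-threaded growth make every forest
bitwise reproducible.

`replicate_forests()` repeats this with per-forest seeds
`base_seed + index` (100 forests by default), retains SNPs with non-zero
VIM% in at least two forests, and records each retained SNP's forest
frequency and mean VIM% over its non-zero occurrences.
`top_frequency_regions()` flags the top half of retained frequencies
(ties at the median included); `evaluate_prediction()` reports the
out-of-bag (estimation) error and the held-out test-cohort (prediction)
error, per class; `intersect_with_gqls()` joins the consensus with the
pFDR-significant association records.

A caveat documented by a regression test: on a 90/10 imbalanced cohort,
balanced weighting narrows the gap between per-class errors relative to
an unweighted forest, but cannot equalize them when the minority class
has only a couple of dozen unique animals — out-of-bag minority samples
then inevitably resemble the majority. Scaled test protocols use 20
forests × 25 trees; the 100 × 75 protocol is the default of the pipeline
and remains a config switch.

## LD, haplotype blocks, and gene mapping

`estimate_ld()` reconstructs two-locus haplotype frequencies from
unphased genotype pairs by EM (double-heterozygote split re-estimated
each iteration; tolerance $10^{-10}$, at most 1000 iterations, genotype
log-likelihood asserted non-decreasing) and reports $r^2$ and $D'$. The
estimate equals the genotype-table MLE — verified against a brute-force
optimizer — so its residual deviation from true phase is the intrinsic
double-heterozygote ambiguity. That ambiguity is negligible for linked
markers in strong LD and material for unlinked pairs; the validation
suite therefore compares EM against direct haplotype counting on 200
phased pairs of 5000 individuals with $|D'| \in [0.65, 1]$, the regime
the block and syntenic screens operate in, where agreement is within
0.02.

`solid_spine_blocks()` implements the solid-spine rule: a run of
consecutive markers is a block when its first and last markers are each
in strong LD with every other member (threshold 0.2 on $r^2$ by default;
$D'$ with the conventional 0.8 available). A left-to-right scan extends
each start to its rightmost valid end and emits maximal non-overlapping
blocks; the implementation is checked against an exhaustive enumeration
oracle on small fixtures.

`map_snps_to_genes()` maps a SNP to a gene when the ±2 Mb window around
the SNP position overlaps the gene body, in 1-based inclusive
coordinates (BED input is converted from 0-based half-open, GFF3 used
as-is); distances are signed to the nearer gene boundary and zero inside
the gene. `syntenic_ld_screen()` estimates $r^2$ for all same-chromosome
pairs of significant and gene-region SNPs, keeping pairs at or above 0.2
regardless of their separation; cross-chromosome pairs are rejected by
definition. LD is computed on whatever cohort is supplied — pass a larger
reference panel when one is available, as small case-control cohorts
estimate $r^2$ noisily.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis assumes, not any
particular breed's demography: 29 autosomes with markers placed uniformly
at random; founders drawn in linkage equilibrium with per-marker allele
frequencies from `founder_maf_range`; descendants by gene dropping with
one uniformly placed crossover per chromosome per meiosis (configurable);
large paternal half-sib families from a small sire pool each generation;
a liability built from a few planted QTL plus a pedigree-cascade
polygenic effect (founders $N(0, \sigma^2_u)$; offspring receive the
parental average plus a Mendelian-sampling term scaled by parental
inbreeding, so the realized covariance is exactly $A\sigma^2_u$) and a
unit-variance residual. The polygenic variance is set jointly with the
realized QTL variance so the underlying-scale heritability equals
`h2_underlying` (default 0.41); drawing QTL effects whose realized
variance already exceeds the target is a configuration error. Affection
status thresholds the realized liability at its empirical
$(1-\text{prevalence})$ quantile, which pins the case count exactly (157
of 265 at the default prevalence 0.5925) — small-cohort tests need
controlled case counts, which the theoretical $\Phi^{-1}$ threshold would
not give. Missingness is completely at random. The default cohort is 265
phenotyped animals from the latest generation, split 40 training / 225
testing.

What the generator does *not* emulate: ancestral LD (founders are in
linkage equilibrium, so background LD between linked markers is weak and
accrues only over the simulated generations), selection, genotyping
error, sex chromosomes, or a realistic site-frequency spectrum. Passing
tests on this cohort therefore demonstrate the statistical machinery —
calibration under the null, power against planted signals, exactness
against oracles — not performance on real cattle data.

## Problem sizes and numerical choices

Routine validation runs use deliberately modest sizes chosen to exercise
every code path: cohorts of 100–265 animals with 30–1200 markers for the
pipeline stages; 2000 animals in 100 half-sib families for heritability
recovery; 200 animals × 1000 markers across 100 seeds for the forest
scan; 200 phased pairs of 5000 individuals for LD. The end-to-end demo
(`run_pipeline()` at defaults, 100 forests × 75 trees) completes in well
under a minute on one CPU and is byte-identical across reruns with the
same seed; all randomness flows from the single config seed, with fixed
offsets separating the pedigree, map, genotype, phenotype and split
draws.

Other numerical conventions: PQL outer tolerance $10^{-6}$ on
$\sigma^2_u$ with at most 200 iterations (non-convergence is an error
carrying the iteration trace) and linear predictors clamped to $\pm 7$
before forming probit weights; the GLS null mean clamped away from 0 and
1 by $10^{-10}$; q-value monotonicity enforced by the tail-minimum
construction; ties at the forest-frequency median included when flagging
regions of interest; the counted allele of a PLINK file is the second
allele observed in file order, recorded in the marker map (MAF and all
test statistics are allele-symmetric, so polarity does not affect
results).

## Known limitations

* PQL attenuation for one-record binary traits (documented above);
  prefer `estimate_h2_binary_lmm()` for calibrated underlying-scale
  estimates at moderate prevalence.
* Single-pass QC is not idempotent in the knife-edge case where an
  animal's call rate straddles the threshold between the original and
  the filtered SNP subset.
* The generator's weak background LD means solid-spine blocks on
  simulated cohorts are sparse; block detection is validated against the
  enumeration oracle and constructed fixtures instead.
* The GQLS working covariance treats kinship as a correlation matrix
  scaled by a single binomial variance function; overdispersion handling
  is a single scalar, not a per-SNP model.
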