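---
title: "Genomic prediction with GWAS-based pre-selection of sequence SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with GWAS-based pre-selection of sequence SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Routine genomic selection in livestock works from medium-density SNP chips
(tens of thousands of markers). Imputed whole-genome sequence (iWGS) data
promise more: if the causal variants for a trait are in the sequence panel
but not on the chip, adding them to the prediction model should raise
accuracy. In practice, adding millions of sequence SNPs wholesale rarely
helps — the signal is diluted and the genomic relationship matrix barely
changes. The strategy this package studies is *pre-selection*: run a
mixed-model GWAS on the sequence panel inside each cross-validation fold,
keep the SNPs passing a suggestive significance threshold, and give them to
the prediction model either pooled with the chip SNPs (one genetic
component) or as their own variance component (two components).

`gpsel` implements the full chain — data simulation, genotype QC and LD
pruning, relationship matrices, REML/BLUP, the association scan, a Bayesian
mixture SNP-effect model, and the cross-validation harness — so the design
can be exercised end-to-end and its statistical behaviour tested.

## Models

**PBLUP / GBLUP.** The base model is the animal model
$$y = 1\mu + Xb + Zg + e,$$
with sex and batch as class effects and age and carcass weight as
covariates. The genetic covariance is $A\sigma^2_u$ (pedigree numerator
relationship matrix, tabular method) for PBLUP, or $G\sigma^2_g$ with the
VanRaden method-1 GRM, $G = WW'/(2\sum_j p_j(1-p_j))$, for GBLUP (columns of
$W$ centered by $2p_j$; missing dosages mean-imputed). The two-component
model adds a second genomic component built from the pre-selected SNPs:
$$y = 1\mu + Xb + Z_1 g_1 + Z_2 g_2 + e,$$
with the total breeding value $g_1 + g_2$. Variance components are
estimated by REML: single-component models are profiled exactly in the
eigenbasis of the kinship matrix (a 1-D optimization of the restricted
likelihood over the variance ratio), two-component models by
average-information REML with an expectation-maximization fallback whenever
an AI step would leave the parameter space or decrease the restricted
likelihood. Convergence requires $|\Delta \ell| < 10^{-8}$ and relative
parameter changes below $10^{-6}$; variances are floored at
$10^{-8}\,\mathrm{var}(y)$.

**Corrected phenotypes.** The association scan and the reliability
computation use phenotypes adjusted for fixed effects,
$y_c = y - X\hat b = \hat g + \hat e$, taken from a single full-data GBLUP
fit on the chip panel. Computing the correction once on all animals mildly
couples folds; this mirrors the study design being reproduced, and
`run_cv(strict_correction = TRUE)` provides a per-fold correction for
methodological comparison.

**GWAS.** Each SNP is tested in
$y_c = 1\mu + x\beta + a + e$, where $a \sim N(0, G_{-c}\sigma^2_a)$ uses a
genomic relationship matrix that *excludes the chromosome of the tested
SNP* (leave one chromosome out), so the polygenic term cannot absorb the
tested signal. The variance components are re-estimated once per
chromosome, not per SNP; each SNP is then tested by generalized least
squares under the fitted covariance with a Wald test against the standard
normal. Significance uses Bonferroni-style thresholds $0.05/N$
(genome-wide) and $1/N$ (suggestive) for $N$ tested SNPs; with the 50,482
SNPs of a typical post-QC 80K chip panel these are 9.90e-7 and 1.98e-5.
Per-SNP variance explained is $\mathrm{PVE} = 2q(1-q)\beta^2/\sigma_p^2$
with $\sigma_p^2$ the variance of the corrected phenotypes in the scanned
set. Significant SNPs on a chromosome are merged into QTL regions bounded
by member positions; a configurable gap (default 10 Mb) splits regions —
the source material reports contiguous spans but states no gap rule, so
the default is a deliberate design choice.

**Bayesian mixture model.** SNP effects follow a four-distribution normal
mixture within each genetic component:
$$a_j \sim \pi_1 N(0, \sigma_4^2/1000) + \pi_2 N(0, \sigma_4^2/100) +
  \pi_3 N(0, \sigma_4^2/10) + \pi_4 N(0, \sigma_4^2),$$
so only the largest-class variance $\sigma_4^2$ is estimated per component.
The mixing proportions are sampled from a Dirichlet with concentration
$(125, 25, 5, 1)$ given the class counts; the chain starts from
$\pi = (0.889, 0.1, 0.01, 0.001)$. Note the starting vector is *not* the
Dirichlet mean ($\approx 0.801, 0.160, 0.032, 0.006$); the Dirichlet
parameters drive the sampling and the vector is only an initial value.
A single-site Gibbs sampler cycles over fixed effects (flat-prior normal
conditionals), per-SNP class indicators (4-way categorical with the effect
integrated out) and effects, $\pi$ per component, $\sigma_4^2$ per
component (scaled inverse-$\chi^2$ pooling all classes through the fixed
ratios) and $\sigma_e^2$. The default chain is 50,000 samples with 10,000
burn-in; the test suite and the pipeline defaults here run 5,000/1,000,
which the ridge-limit check shows is ample at these problem sizes. The
class-1 variance is literally $\sigma_4^2/1000$ — near-null, not a point
mass at zero.

Hyperparameters the source material does not state: the largest-class
variance prior is scaled inverse-$\chi^2$ with df 4.2 and scale chosen so
the prior-mean total genetic variance equals half the phenotypic variance
(split across components and classes by the starting $\pi$); the residual
prior is weakly informative (df 2, scale $\mathrm{var}(y)/2$). Both are
exposed in `mixture_spec()`.

**Reliability.** For each validation fold,
$r^2 = \mathrm{cor}(\widehat{\mathrm{GEBV}}, y_c)^2 / h^2$, with the $h^2$
denominator taken from the full-data chip GBLUP REML fit (the most natural
reading of an unqualified "the trait heritability"). The standard error of
an approach is the SD of its five fold reliabilities over $\sqrt 5$.

## The synthetic population

The generator emulates, at desk scale, a pig cohort of 482
growing-finishing animals from 80 sires and 226 dams:

* **Founder haplotypes** are mosaics over a small ancestral pool (default
  6 haplotypes per chromosome); the active pool haplotype switches between
  adjacent SNPs with probability $1 - \exp(-d/\text{block mean})$ (default
  block mean 100 kb). This gives adjacent-SNP LD that decays with physical
  distance — with the default 10 kb spacing, mean adjacent $r^2 \approx
  0.15$ with a high-LD tail, in the range seen on livestock chips — without
  requiring a coalescent simulator.
* **Gene dropping** through a two-generation pedigree (sires and dams drawn
  with replacement) with recombination at 1 cM/Mb.
* **Panels**: the dense ("sequence-like") panel is all simulated SNPs
  passing the MAF floor; the chip is an evenly spaced subset (default one
  third). The genome itself is scaled down — 6 chromosomes of 400 SNPs —
  so a full nine-approach cross-validation study runs in minutes; all
  sizes are configuration fields.
* **QTLs** are planted on dense-panel SNPs *not* on the chip (default four,
  each explaining 2.5% of phenotypic variance). This is deliberate: the
  premise of pre-selection is that causal sequence variants are absent from
  the chip, and with on-chip QTLs the pre-selection approaches have nothing
  to add. Effects satisfy $2q(1-q)b^2/\sigma_p^2 = \mathrm{PVE}$ exactly at
  the realized allele frequency, so recomputing PVE from the truth bundle
  round-trips to machine precision.
* **Phenotype**: mean 1.91 (% units), CV 0.3173, $h^2 = 0.26$; sex and
  batch effects of about 0.3 phenotypic SD (magnitudes are stated choices,
  not estimates — they only need to be non-zero for the adjustment
  machinery to be testable), small age and carcass-weight slopes. The
  polygenic background (marker effects on all non-QTL dense SNPs) is
  rescaled so realized $\mathrm{var(TBV)}/(\mathrm{var(TBV)} + \sigma_e^2)$
  hits the target $h^2$ exactly, and the truth bundle records breeding
  values, QTL positions/effects and the variance bookkeeping for
  parameter-recovery tests.
* **Reproducibility**: one seed fans out to named substreams (haplotypes,
  pedigree, effects, noise), so outputs are byte-identical under a fixed
  seed.

What the generator does **not** emulate: coalescent site-frequency spectra,
sequencing or imputation errors (the "sequence" panel is error-free truth),
selection, assortative mating, X chromosomes, multi-generation pedigrees.
Passing tests therefore show the estimators are correct and the design
behaves as intended under its own assumptions — not that real iWGS data
will deliver the same gains.

## Numerical choices

* GRM: VanRaden method 1 with allele frequencies observed in the full
  genotyped set (not per fold), matching how a single GRM is reused across
  cross-validation in practice.
* Mixed-model equations get a $10^{-6}$ diagonal jitter when the smallest
  eigenvalue of the covariance falls below $10^{-8}$.
* LD pruning resolves violating pairs (within a 50-kb physical window,
  $r^2 \ge$ cutoff — so cutoff 1.00 still removes perfect duplicates)
  deterministically: highest-$r^2$ pair first, lower-MAF member removed, on
  a MAF tie the later-position SNP. This global rule is what the test
  suite's brute-force oracle checks; a windowed traversal order would not
  change the invariant (no violating pair survives) but could change which
  member goes, so the package fixes the global rule.
* QC iterates SNP-filter → individual-filter → MAF recomputation to a
  fixed point, making the filter idempotent.
* Missing dosages: mean-imputed for GRMs, scans and marker models;
  pairwise-complete for $r^2$.
* Monomorphic SNPs in a scan are emitted with $\beta = 0$, $p = 1$ and a
  flag rather than dropped, keeping row counts stable.
* An empty pre-selection degrades two-component approaches exactly to
  their one-component chip counterpart (tested).

## Problem sizes used by the shipped studies

`h2_recovery_study()` defaults to 30 replicates of $n = 482$ with a
5,000-SNP chip; `gwas_null_calibration()` to 1,000 null scans at $n = 150$;
`gwas_power_study()` to 50 replicates at $n = 482$;
`reliability_ordering_study()` to 20 replicates of the full default
configuration (482 animals, ~2,400 dense SNPs). These sizes were chosen so
each study finishes in minutes on one core while leaving the Monte-Carlo
error well below the effects being measured.

## Known limitations

* The AI-REML path reports `converged = FALSE` rather than failing when a
  boundary solution makes progress slow; callers should check the flag.
* The Gibbs sampler is single-chain by design; it reports thinned variance
  traces but no formal convergence diagnostics.
* Reliabilities on 5 folds of a few hundred animals are noisy (per-fold
  values above 1 occur); conclusions should rest on replicate averages, as
  in `reliability_ordering_study()`.
* The pipeline's "iWGS" panel is the merged chip+dense panel of the
  simulator; real imputation dosage uncertainty is out of scope.
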