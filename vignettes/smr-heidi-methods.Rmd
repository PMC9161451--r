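---
title: "Summary-data Mendelian randomization and the HEIDI test: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-data Mendelian randomization and the HEIDI test: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrkit)
```

## The problem

Genome-wide association studies (GWAS) identify loci associated with a
trait, but rarely the gene whose altered expression mediates the
association. Expression QTL (eQTL) studies identify variants associated
with gene expression. smrkit integrates the two sets of summary statistics
— no individual-level phenotype data required — through an
instrumental-variable argument: if a variant affects expression of a gene
and that expression affects the trait, the variant's trait effect should be
proportional to its expression effect.

## The SMR model

Let $b_{zx}$ be the effect of instrument SNP $z$ on expression $x$
(estimated by the eQTL study) and $b_{zy}$ its effect on the trait $y$
(estimated by the GWAS). Under the causal (or pleiotropic) model the Wald
ratio

$$\hat b_{xy} = \frac{\hat b_{zy}}{\hat b_{zx}}$$

estimates the effect of expression on the trait. Its significance is
assessed with the chi-square(1) statistic

$$T_{SMR} = \frac{z_{zy}^2 \, z_{zx}^2}{z_{zy}^2 + z_{zx}^2},$$

where $z^2$ are the squared association z-scores. $T_{SMR}$ is a harmonic
combination: it never exceeds the weaker of the two signals, so a gene is
only called when both the eQTL and the GWAS associations are strong. When a
source table supplies only p-values, the z-scores are recovered through the
inverse normal quantile at $p/2$ (`z_from_p()`, accurate to $p = 10^{-300}$;
censored entries such as `<1e-300` are parsed at their bound and flagged).
When betas and p-values are both present and disagree through rounding, the
beta/SE route takes precedence.

The delta-method standard error of the ratio is
$SE(\hat b_{xy}) = |\hat b_{xy}|\sqrt{SE_{zy}^2/\hat b_{zy}^2 +
SE_{zx}^2/\hat b_{zx}^2}$, reported as `NA` when $\hat b_{zy} = 0$.

## Instrument eligibility and harmonization

Only cis SNPs — strictly closer than 1 Mb to the gene probe — are
considered, and a probe is testable only if its best cis-eQTL reaches
$p \le 5\times 10^{-8}$ (inclusive at the boundary). Before any statistic is
computed every dataset is oriented to the reference panel's allele-1:
records with reversed allele order have their effect negated and frequency
reflected; non-matching pairs are retried after strand complementation;
irreconcilable pairs are dropped and logged. Strand-ambiguous pairs (A/T,
C/G) cannot be oriented from alleles alone: they are dropped when the minor
allele frequency exceeds 0.4 in any source (near 0.5 the orientation is
statistically undecidable) and otherwise resolved by choosing the
orientation whose frequency best matches the panel. An effect-allele
frequency concordance check (maximum absolute difference 0.2, applied to
all three pairs of sources) and a MAF $\ge 0.01$ filter (strict `<`
removal, in any source) complete the SNP-level QC. Every exclusion is
written to a drop log with a reason; no SNP is silently lost. When a GWAS
file carries no allele frequencies, the reference-panel frequency is
substituted — the standard workaround for consortia that do not release
frequency data.

The reference panel itself passes the standard QC in a fixed order so
removal counts are reproducible: marker call rate $\ge$ 95%, MAF $\ge$ 5%,
Hardy–Weinberg chi-square $p \ge 10^{-6}$, then individual call rate
$\ge$ 95%. HWE is the 1-df goodness-of-fit chi-square rather than the exact
test: it is closed-form, deterministic, and indistinguishable from the
exact test at panel-scale counts. The HWE criterion is applied as an
exclusion of extreme departures (removing $p < 10^{-6}$), the only reading
under which the filter retains well-genotyped variants.

## The HEIDI test

A significant $T_{SMR}$ does not distinguish one variant affecting both
expression and trait (pleiotropy, the interesting case) from two distinct
variants in LD, one affecting each (linkage). Under the single-variant null
every cis SNP in LD with the causal variant estimates the *same* ratio
$b_{xy}$, so heterogeneity among the per-SNP ratios indicates linkage.

For each non-top instrument $i$, HEIDI forms
$d_i = \hat b_{xy}(i) - \hat b_{xy}(\mathrm{top})$. The covariance of the
$d$ vector follows from the delta method with
$\mathrm{Cov}(\hat b_{zy,i}, \hat b_{zy,j}) = r_{ij}\,SE_i\,SE_j$ within
each study (the LD-induced covariance of marginal estimates from one
cohort), signed LD $r_{ij}$ taken from the panel after harmonization, and
zero cross-covariance between the GWAS and eQTL studies. The statistic
$T_{HEIDI} = \sum_i (d_i/SD(d_i))^2$ is referred to its null distribution
$\sum_k \lambda_k \chi^2_1$, with $\lambda_k$ the eigenvalues of the
correlation matrix of $d$. Numerically singular correlation matrices are
ridge-regularized (diagonal $+10^{-8}$, recorded in the result).

Instruments are selected with $0.05 \le r^2 \le 0.90$ against the top SNP
(near-duplicates of the top SNP contribute no independent information and
destabilize the covariance; unlinked SNPs carry no shared signal), an eQTL
p-value below $1.57\times 10^{-3}$ ($|z| > 3.16$; weaker instruments make
the ratio estimate unstable), pairwise pruning — any remaining pair whose
mutual $r^2$ leaves the same window drops its weaker-eQTL member — and a
cap of 20 instruments. At least 3 instruments are required; below that the
HEIDI p-value is reported absent rather than unreliable. These selection
constants are exposed as arguments.

The weighted-chi-square tail is computed by Imhof's numerical inversion of
the characteristic function. The integrand is oscillatory with an
algebraically decaying envelope, so the integral is accumulated over
geometrically growing finite segments rather than in one quadrature over
$(0,\infty)$, which can silently misconverge. Because the inversion is
additive around $1/2$ it resolves tail probabilities only to absolute
precision; results below $10^{-8}$, and any non-convergent integral, defer
to a Satterthwaite moment-matching approximation (a scaled chi-square
matching the first two moments), which is log-accurate in the far tail.
The method actually used is recorded on each result.

## Pipeline gating

Per GWAS dataset: every probe is harmonized and tested; the number of
probes with a valid SMR p-value defines the Bonferroni denominator
($\alpha/n$, with $\alpha = 0.05$); HEIDI runs only for Bonferroni
survivors; a gene passes the pleiotropy screen when $p_{HEIDI} \ge 0.05$
(HEIDI *rejection* means heterogeneity, i.e. linkage). Probes whose best
cis-eQTL misses eligibility are reported `not_testable` and consume no
Bonferroni budget — consistent with analysis-specific thresholds arising
when the same $\alpha$ is divided by slightly different probe counts.

## The synthetic-data generator

The generator makes every stage verifiable without external data. It
simulates a cis locus of $m$ SNPs with MAFs drawn uniformly from
$(0.1, 0.5)$ and LD from an AR(1) Gaussian copula: latent haplotype values
with correlation $\rho^{|i-j|}$ are thresholded at the MAF quantile and two
haplotypes summed to a dosage. Thresholding attenuates the dosage
correlation relative to the latent $\rho$; the attenuation is measured
empirically in the test-suite, never assumed. Three independent samples
share one LD model: an expression cohort, a trait cohort, and a reference
panel — mirroring the two-study-plus-panel structure of a real analysis.

Phenotypes follow the generative models the method assumes. Expression is
$x = b_{zx} g_1 + \varepsilon_x$. The trait is, per architecture:
pleiotropy $y = b_{xy} b_{zx} g_1 + \varepsilon_y$ (the genetically
determined part of expression, mediated to the trait); linkage
$y = b_{zy2} g_2 + \varepsilon_y$ with $g_2$ a *different* SNP in LD with
$g_1$; null, pure noise. The trait is quantitative: meta-analytic GWAS
effects arrive on heterogeneous scales anyway, and a linear trait keeps the
IV identity $b_{zy} = b_{xy} b_{zx}$ exact and calibration interpretable.
Case/control generation is out of scope.

Default study conditions: cohorts of 5,000 (20,000 for parameter-recovery
studies), a 500-individual panel (a realistically modest panel, the same
order as typical genotyped reference cohorts), 20 SNPs spaced 5 kb inside
the cis window, $b_{zx} = 0.5$ (a strong cis-eQTL, as top cis-eQTLs are),
$b_{xy} = 0.3$, $b_{zy2} = 0.3$, $\rho = 0.85$ with adjacent causal
variants under linkage — realizing a dosage correlation of about $r = 0.6$
between the two causal SNPs after copula attenuation. Allele pairs are
drawn from the non-complementary combinations so that generated scenarios
are deterministic under harmonization; strand-ambiguity handling is
exercised by dedicated tests instead.

What the generator does *not* emulate: missing genotypes in cohorts,
population stratification, imputation noise, multi-causal expression
architectures, and case/control ascertainment. Passing calibration here
shows the statistics are correct under the model's own assumptions, not
that real data meet them.

## Numerical and design choices

- Replicate studies (`replicate_smr()`, `replicate_heidi()`) draw a fresh
  locus and fresh cohorts per replicate and, because generated data are
  orientation-consistent by construction, assemble the joint per-SNP table
  directly; the full file-based path including allele alignment is
  exercised separately. Study sizes used by the shipped checks: 2,000
  replicates at $n = 5{,}000$ per cohort for SMR type-I error and HEIDI
  calibration/power; 200 replicates at $n = 20{,}000$ for recovery of
  $b_{xy}$.
- Ties in top-SNP selection break by larger eQTL $|z|$, then
  lexicographic SNP id — fully deterministic output ordering throughout
  (position, then id), so identical configurations give byte-identical
  result files.
- p-values are floored at the smallest positive double rather than
  underflowing to 0, preserving the $(0,1]$ contract.
- Monomorphic variants: HWE p-value 1 by convention; association records
  flagged with undefined SE; LD with a zero-variance column is an error
  rather than a silent `NA`.
- The per-SNP regression in `summarize_cohort()` uses the exact t
  distribution at all sample sizes (cheap, and exact where the normal
  approximation would be marginal).

## Known limitations

Single-exposure, single-probe-at-a-time inference; no multi-SNP SMR
extension; no trans-eQTL support; no colocalization-style posterior
probabilities; biallelic SNPs only; autosomal analysis only. The HEIDI
delta-method covariance is first-order — with very weak instruments the
test can be slightly conservative, which is why the instrument p-value
threshold exists.
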