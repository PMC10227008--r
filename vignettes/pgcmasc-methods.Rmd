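---
title: "Methods: sex-specific expression, top-k enrichment, and the repeat methylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific expression, top-k enrichment, and the repeat methylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pgcmasc` asks whether a prenatal exposure shifts the transcriptome of
female fetal germ cells toward the male program. The analysis has four
statistical layers — normalization, differential expression, a ranked-list
enrichment statistic with a permutation/gamma null, and a descriptive
repeat-methylome module — all exercised on synthetic data with known ground
truth. This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
establish about real data.

# Count model and normalization

Counts are modeled as negative binomial: for gene $g$ and sample $j$,
$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g)$ with
$\mathrm{Var}(y) = \mu + \phi \mu^2$ and
$\log \mu_{gj} = \beta_{g,\mathrm{group}(j)} + \log(\mathrm{eff.lib}_j)$.

**TMM factors.** Between-sample normalization follows the trimmed mean of
M-values with the conventional defaults: reference sample by the
75th-percentile rule; per-pair M and A statistics on relative abundances,
genes zero in either member excluded; two-sided trimming of 30% on M and 5%
on A by rank; inverse delta-method-variance weighting; factors rescaled to
geometric mean 1. Two numerical notes:

* Trimming uses first-occurrence ranks, so ties at the trim boundary are
  resolved by input order — deterministic under a fixed gene order.
* Rescaling one sample's counts by a constant leaves M, A and the trimmed
  set exactly invariant, but the per-gene weight sums delta-method terms
  from *both* samples and only one of them rescales; the factor therefore
  moves by $O(1\%)$. Exact invariance holds only when the two columns are
  proportional. This is a property of variance-weighted TMM generally, not
  of this implementation.

**CPM.** Reported normalized values are counts per million by effective
library size plus a pseudo-count `prior` (default 0.5) applied on the CPM
scale, so zeros map to `prior` and rescaling all counts and library sizes
jointly leaves values unchanged.

# Dispersion estimation

Gene-wise dispersions are estimated by the method of moments on
library-size-normalized counts $z_{gj} = y_{gj}/s_j$ (with $s_j$ the
relative effective library size). Within each design cell the moment
equation is $\mathrm{E}(v_i) = h_i m_i + \phi m_i^2$, where $h_i$ is the
cell mean of $1/s_j$ — the exact Poisson-part coefficient after
normalization (approximating $h_i$ by 1 biases $\phi$ upward when library
sizes vary). Pooling cells and using the unbiased estimate
$m_i^2 - v_i/n_i$ of $\mu_i^2$ in the denominator gives the raw per-gene
estimate, floored at zero.

Raw estimates at a handful of residual degrees of freedom are extremely
noisy, so they are shrunk toward a common dispersion with weight
$w = n_0/(n_0 + \mathrm{df_{resid}})$, $n_0 = 10$ by default. The common
dispersion is the *pooled* moment ratio over all genes rather than the
median of the per-gene estimates: per-gene moment estimates at low df are
right-skewed and the zero floor further distorts their median downward,
which in turn under-disperses the likelihood-ratio test and inflates its
type-I error; the pooled ratio is read-weighted and nearly unbiased. With
this choice the null type-I error of the LRT at the package's reference
condition (2000 genes, 5 samples per group) centers on the nominal 0.05.

# Differential expression

Each gene is fitted by Fisher scoring for the one-way log-link NB GLM with
fixed $\phi_g$ and offsets $\log(\mathrm{eff.lib}_j)$; the fit is
vectorized across genes (one mean parameter per design cell). Numerical
choices: step damping to $\pm 5$ on the log scale, convergence when the
step falls below $10^{-10}$, 100 iterations maximum (non-converged genes
are flagged and reported with $p = 1$), and cells with all-zero counts
pinned at a mean of $10^{-10}$ counts. The statistic is
$\mathrm{LRT} = 2(\ell_{\mathrm{full}} - \ell_{\mathrm{reduced}})$ with a
$\chi^2$ reference on the difference in cell counts; genes with all-zero
counts across the contrast are excluded from testing and from the
Benjamini–Hochberg denominator. As $\phi \to 0$ the statistic reduces to
the Poisson GLM LRT (verified against `stats::glm` to $10^{-4}$, and
against a fixed-dispersion NB family fit to $10^{-6}$).

Sex-specific sets use the study criteria — FDR < 0.05 and more than
two-fold change — on the male-vs-female vehicle contrast; positive log2FC
means male-high, and fold changes come directly from the GLM coefficients
without shrinkage (the threshold applies to that value). Exposure lists
order *all* tested genes by ascending p-value with deterministic
tie-breaking (descending |log2FC|, then lexicographic gene id, radix
order), so rankings are invariant under permutation of the input genes.

# The enrichment statistic and its null

The expressed universe is the set of genes whose maximum raw count strictly
exceeds 100 across the in-scope samples (default threshold; "exceeds"
means a count of exactly 100 is excluded). Both the ranked list and the
sex-specific sets are intersected with this universe before the curve is
computed, so the observed fractions and the permutation null share one gene
space. The curve is the exact cumulative fraction
$\mathrm{frac}(k) = |top_k \cap S|/k$ for $k \le 200$.

The null samples $s$ genes from the universe *without replacement* —
"sampling a set of genes" implies distinct genes, and it makes the exact
hypergeometric law available as an oracle: the number of set members in a
draw is $\mathrm{Hypergeometric}(N, K, s)$. 5000 iterations are drawn per
$s \in \{50, 100, 200\}$ from a seeded generator, and the fraction
distribution is summarized two ways:

* a gamma fit by moment matching, $\alpha = m^2/v$, $\beta = m/v$, with the
  unbiased ($n-1$) sample variance; the fit is refused (and the null
  flagged degenerate) when the draws have zero variance, in which case
  empirical quantiles are used downstream;
* empirical tail probabilities and quantiles.

**Known limitation.** The gamma fit matches the bulk and the 95th
percentile of the permutation distribution well, which is what the per-k
flags use. Far in the tail it is conservative-in-reverse: at the default
calibration (N = 3100, K = 140) the analytic $P(\mathrm{frac} > 0.10)$ is
roughly 0.05 at $s = 50$ and overestimates the exact hypergeometric tail by
an order of magnitude at $s = 200$. Tail probabilities reported by the
package therefore carry the empirical estimate alongside the gamma value,
and the exact `hypergeom_tail()` is available whenever the question is a
pure tail probability.

**Per-k calls.** Each observed $\mathrm{frac}(k)$ is compared with the
gamma-fit $1-\alpha$ quantile of the null at the nearest calibrated $s$
($k < 50$ uses $s = 50$). At $k$ equal to a calibrated size the call is an
exact-level test; for $k$ between sizes the larger-$k$ fraction has smaller
variance than the matched null, making the call conservative; for $k$ well
below 50 the observed fraction is coarse (multiples of $1/k$) and the call
is anti-conservative. For this reason the *summary* criterion ("sustained
enrichment") evaluates flags over a configurable k-range defaulting to
5–50: below $k = 5$ a single non-set gene at the top of the list forces
$\mathrm{frac} = 0$ regardless of enrichment strength, so per-k flags there
measure resolution, not biology. Per-k flags are still computed and
exported for every $k$. No multiplicity correction is applied across $k$;
the per-k flags are descriptive, as in the figure style they mirror.

# Synthetic data

The count generator draws baseline gene means log-normal with spread
`baseline_sdlog = 2` (a typical bulk RNA-seq dynamic range) and the mean-log
set by closed-form quantile matching so that an expected `universe_target`
out of `n_genes` baselines exceed the expression threshold — deterministic
control of the universe size without rejection sampling. Since the universe
is defined on the *maximum* count across samples, the realized universe
overshoots the target somewhat; the calibration is on the baseline scale.

Defaults mirror the study conditions at the gene level — 15,423 genes,
universe target 3100 over threshold 100, 1862 male-specific and 1669
female-specific genes — combined with a desk-scale sample profile: one
generation and five samples per sex-by-dose cell for the default, the
three-generation grid as an option. Sex dimorphism (`sex_log2fc`, default 2
log2 units, i.e. four-fold — comfortably above the two-fold calling
threshold) is applied symmetrically: half up in the favoured sex, half down
in the other, so the male and female sets are balanced by construction.
The masculinization signal up-shifts a random `masc_fraction` (default 0.5)
of male-specific genes by `masc_effect` (default 1.5 log2 units) in every
exposed female sample, independent of dose level — the simplest shape of
the effect; dose-response profiles are out of scope. Library-size factors
are log-normal(0, 0.25) and dispersions gamma(2, 20) (mean 0.1) — the
study does not report these distributions, so the defaults are conventions
chosen to look like routine bulk RNA-seq of sorted cells, flagged as such.

The methylation generator lays non-overlapping repeat loci end-to-end on a
synthetic chromosome (families interleaved by a seeded shuffle), places
CpGs every 20 bp, draws Poisson(20) read depths, and draws methylated reads
binomially from the locus-level methylation: IAP-like 0.80, LINE-1-like
0.15, SINE-like 0.05, with an exposure shift of +0.30 on half of the
B3-like loci. The set of shifted loci depends only on the configuration
seed, so exposed and unexposed runs shift the same loci.

What passing tests on these data *do* show: the estimators recover the
parameters they target at the configured effect sizes and depths, the null
machinery is calibrated against its exact law, and the full pipeline
detects the planted masculinization with the claimed power. What they do
*not* show: robustness to litter/dam correlation (not modeled, and the
exposure contrasts do not adjust for it), batch structure, outlier
samples, count-model misspecification, or single-cell/zero-inflation
structure — none of which the generator emulates.

# Repeat methylome

CpG calls join every annotation interval containing them under the 0-based
half-open convention (conversions from 1-based Bismark coverage happen only
at the I/O boundary); nested or overlapping loci each receive the call, and
a call is counted once per family even when it lies in several loci of that
family. Family-level methylation is pooled-read weighted
($\sum \mathrm{meth} / \sum \mathrm{reads}$), robust to uneven depth;
per-locus fractions are available separately for distributional summaries.
Rankings require at least `min_cpg = 50` covered CpGs so single-CpG
families cannot top the tables; ties break lexicographically. Strand is
ignored throughout (calls are assumed destranded). The "coverage" metric
counts covered CpGs; counting covered loci instead is exposed through the
per-locus interface.

# Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the caller's
RNG state; the pipeline derives fixed per-stage child seeds from one global
seed and records them in a JSON manifest, and two runs of the same
configuration produce byte-identical artifacts (no timestamps are written).
The test suite and the acceptance script run the statistical checks at
desk-scale sizes chosen as the package's reference conditions: null
calibration at the full universe (3100/140, 5000 draws); type-I error on
2000-gene, 5-per-group null simulations averaged over 10 replicates
(replicates share library and dispersion draws within a run, so averaging
across simulations is the correct way to estimate the rate); and
masculinization power over 20 seeded replicates at 3000 genes. The
full-scale gene universe (15,423 genes) is the generator default and runs
in the same code paths.
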