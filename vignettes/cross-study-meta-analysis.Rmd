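---
title: "Cross-study meta-analysis of differential expression: models and methods"
author: "degmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study meta-analysis of differential expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degmeta)
```

## The problem

Independent RNA-seq studies of the same biological contrast routinely
disagree: study-specific husbandry, handling and technical factors can move
expression profiles more than the contrast under study, so per-study lists of
differentially expressed genes (DEGs) overlap poorly and even flip direction.
The motivating setting is the sea-anemone *Aiptasia* symbiosis literature,
where several studies compare aposymbiotic (symbiont-free) and symbiotic
animals on the same clonal host line, yet samples cluster by experiment
rather than by symbiotic state. `degmeta` provides the statistical machinery
to (i) quantify that batch structure, (ii) combine the per-study evidence
into a single, better-calibrated effect estimate per gene, and (iii) test
whether the combined gene set is more condition-associated than equally
sized subsets of any single study's DEGs.

Everything is exercised against a synthetic multi-study generator with known
ground truth, so each stage's statistical claims are testable without any
external download.

## Per-study effect sizes

For gene $g$ in study $i$, the effect size is the natural-log ratio of
geometric means,
$$T_i = \ln \frac{\mathrm{geomean}(x_{\mathrm{apo}} + c)}{\mathrm{geomean}(x_{\mathrm{sym}} + c)},$$
computed as the difference of group means of $\log(x + c)$ with pseudocount
$c = 0.01$ TPM (geometric means are undefined at zero; 0.01 is far below
biologically meaningful abundance). The sign convention is fixed
pipeline-wide: $T_i > 0$ means higher expression in aposymbiotic animals,
reported as *downregulated in symbiotic* animals.

The standard error is the Welch form
$\mathrm{SE}_i = \sqrt{s^2_{\mathrm{apo}}/n_{\mathrm{apo}} + s^2_{\mathrm{sym}}/n_{\mathrm{sym}}}$
on the log scale, and the per-study p-value uses the normal approximation
$z = T_i/\mathrm{SE}_i$. This is a deliberately simple stand-in for a full
quantification-aware differential-expression fit: the downstream
meta-analysis consumes only $(T_i, \mathrm{SE}_i, n_i)$, and externally
computed summary tables (columns `gene`, `b`, `se_b`, `n`) can be supplied
through `read_summary_table()` whenever fidelity to a particular upstream
fitter is wanted.

Two conventions deserve explicit mention:

* **The meta-analysis variance.** The within-study variance passed to the
  random-effects model is $v_i = \mathrm{SE}_i^2 \cdot n_i$, with $n_i$ the
  total number of replicates in study $i$ (both conditions). This
  convention is unusual — $\mathrm{SE}^2$ already reflects sample size — but
  it is the contract this pipeline implements; the conventional
  $v_i = \mathrm{SE}_i^2$ is available via `variance = "se_sq"` in
  `study_effect_sizes()`, and a per-condition reading of $n_i$ (the smaller
  group size) via `n_definition = "per_condition"`. Because $v_i$ enters
  every study's weight in the same way, the rescaling mostly cancels in the
  combined point estimate but widens its standard error, making the
  meta-analysis conservative.
* **Normal approximation at small $n$.** With 4–5 replicates per group the
  normal tail is lighter than the $t$ tail, so per-study p-values are
  liberal in the extreme tail; in null simulations roughly 1% of genes are
  flagged at a within-study $q < 0.05$. The meta-analysis stage, with its
  across-gene Benjamini–Yekutieli correction and two-study eligibility
  requirement, restores control (empirical FDR in simulations is
  effectively zero — see the package's acceptance checks).

Genes with zero log-scale variance in both groups are flagged
(`zero_var`), never silently dropped; a flagged gene with $T = 0$ gets
$p = 1$.

## DerSimonian–Laird random-effects combination

Per gene, studies are combined with the DerSimonian–Laird method-of-moments
estimator. With fixed-effect weights $w_i = 1/v_i$ and
$\bar T = \sum w_i T_i / \sum w_i$:

$$Q = \sum_i w_i (T_i - \bar T)^2, \qquad
  C = \sum_i w_i - \frac{\sum_i w_i^2}{\sum_i w_i}, \qquad
  \tau^2 = \max\!\left\{\frac{Q - (k-1)}{C},\ 0\right\}.$$

The combined effect uses random-effects weights $w_i^* = 1/(v_i + \tau^2)$:

$$m^* = \frac{\sum_i w_i^* T_i}{\sum_i w_i^*}, \qquad
  \mathrm{SE}(m^*) = \frac{1}{\sqrt{\sum_i w_i^*}}, \qquad
  p = 2\left[1 - \Phi\!\left(\frac{|m^*|}{\mathrm{SE}(m^*)}\right)\right].$$

$Q$ is computed with fixed-effect weights (the standard DL reading);
$\tau^2 = 0$ reduces the combination exactly to the fixed-effect
inverse-variance estimate, a property the test suite asserts. Across genes,
p-values are corrected with the Benjamini–Yekutieli procedure
(`bhy_adjust()`), the arbitrary-dependence variant that multiplies the
Benjamini–Hochberg bound by the harmonic number $c(m) = \sum_{h=1}^m 1/h$ —
appropriate because per-gene tests across a transcriptome are arbitrarily
dependent. Plain BH is available by flag.

**Eligibility.** By default a gene enters the meta-analysis when it is
significant (within-study $q < 0.05$) in at least two studies; the looser
"valid estimate in at least two studies" rule is available as
`eligibility = "estimable"`. Eligible genes are then combined over *all*
studies with valid estimates, not only the significant ones. Rows with
$\mathrm{SE} = 0$ are excluded from the combination (their fixed-effect
weight would be infinite) and counted in a message. Genes significant in
opposite directions in different studies are still combined: discordance is
something the concordance module measures, not an exclusion rule.

## Concordance classification

`overlap_classify()` reports, for the genes flagged in every study, how many
agree in direction (up or down in symbiotic animals everywhere) and how many
are discordant, with the discordant percentage of the overlap to one
decimal. `concordance_summary()` builds the same object directly from class
counts, which is how the package reproduces the published four-study worked
example (166 up + 134 down + 93 discordant = 393 overlapping genes, 23.7%
discordant).

## QC: normalization, PCA, rank correlation

`normalize_intersample()` applies median-of-log-ratios scaling (the
size-factor method of count-based differential-expression tools, applied
here to TPM matrices): the reference is the per-gene geometric mean across
samples, each sample's factor is the median ratio to that reference over
genes positive in all samples, and factors are rescaled to geometric mean 1
— which makes the operation exactly idempotent. `pca_samples()` and
`kendall_matrix()` (tie-corrected Kendall $\tau_b$, since TPM ties at zero
are common) provide the sample-relationship diagnostics; in batch-dominant
data the silhouette of the study labelling in PC space exceeds that of the
condition labelling, and the test suite asserts exactly that on synthetic
data.

## PVCA: partitioning variance among experimental factors

`pvca_partition()` implements principal variance component analysis:

1. restrict to the gene subset, transform $\log_2(x + 0.5)$, and center
   each gene (no unit-variance scaling by default — scaling down-weights
   genes whose realized factor effects are large and demonstrably biases
   the partition; a `scale_genes` switch restores it);
2. eigen-decompose the sample–sample covariance;
3. retain the smallest set of leading PCs whose cumulative eigenvalue share
   reaches `pc_var_threshold`;
4. on each retained PC score, estimate a one-way random-effects variance
   component per factor by REML, each factor fitted *independently* (a
   joint mixed model is fragile when factors are mutually confounded, as
   study-level husbandry variables nested in study always are); the per-PC
   residual is the score variance the factors do not absorb;
5. average per-PC fractions weighted by each PC's eigenvalue share of the
   **total** variance, attributing the unretained share to the residual.

Step 5 is the one genuinely open design choice. Renormalizing over retained
PCs only (the common shortcut) inflates structured factors and can report a
near-zero residual even for noisy data; attributing unretained variance to
the residual keeps the output a true decomposition of total variance, makes
i.i.d. noise yield a residual fraction near 1, and lets known simulated
variance components be recovered on their natural scale. Fractions always
sum to one.

The REML routine (`reml_oneway()`) exploits the one-way structure for a
closed-form profiled likelihood in the ratio
$\theta = \sigma^2_a/\sigma^2_e$, optimized in one dimension with the
boundary $\theta = 0$ checked exactly. It matches `lme4::lmer` to four
decimals in the test suite and is fast enough for the Monte-Carlo loop
below (a full PVCA on 34 samples takes milliseconds).

**Choosing the retention threshold.** The default is 0.6, a common PVCA
convention. But note the interaction with strong batch structure: if the
batch components alone exceed the threshold, the condition axis is never
retained and its fraction is reported as 0. In the recovery analyses below
the three study contrasts carry ~2/3 of the variance, so those analyses use
a threshold of 0.8, which retains the condition component as well. When
batch effects dominate, raise the threshold until the factors of interest
are inside the retained span (the `per_pc` matrix in the result shows which
factors each PC loads on).

## The Monte-Carlo gene-subset null

A smaller gene list tends to have a larger condition-variance fraction, so
comparing the meta-analysis DEG set against full per-study DEG lists would
be unfair. `mc_gene_subset_test()` draws `subset_size` genes without
replacement from each per-study DEG list, runs the identical PVCA on each
draw, and compares the observed condition fraction against this null. The
empirical p-value uses add-one smoothing, $p = (r + 1)/(N + 1)$ with $r$
the number of null draws at or above the observed statistic, so $p$ is never
exactly zero; the raw count $r$ is reported alongside so statements of the
form "0 of $N$ trials exceeded the observed value" can be made verbatim.
With a fixed seed the result is bit-reproducible.

## The synthetic generator

`generate_multistudy()` draws, on the natural-log scale,

$$\log x_{gj} = \mu_g + \sum_f e_{g,\,\ell_f(j)} + \tfrac{1}{2}\,s_j\,\delta_g + \varepsilon_{gj},$$

with per-gene baseline $\mu_g$, per-factor level effects $e$, a signed
condition effect $\delta_g$ on a core subset of genes
($s_j = +1$ for aposymbiotic, $-1$ for symbiotic samples), and i.i.d. noise
$\varepsilon$, exponentiated to strictly positive TPM-like values. Key
properties:

* **Exact moment control.** Each gene's factor-level effects are
  weighted-centered and rescaled so their realized per-sample variance
  equals the configured $\sigma_f^2$ exactly (raw draws with $k$ levels
  would realize only $\sigma_f^2(1 - 1/k)$ on average). Likewise the
  symmetric $\pm\delta_g/2$ coding makes the condition's per-sample
  variance exactly $\delta_g^2/4$ and the true log ratio exactly
  $\delta_g$. Variance-component recovery therefore has a sharp truth.
* **Defaults emulate the motivating design**: 4 studies contributing
  (4, 5, 4, 4) replicates per condition — 17 samples per symbiotic state —
  a dominant study factor (sd 1.5 on the log scale) plus five study-level
  husbandry factors (feeding frequency, days after feeding, water, light,
  temperature), each taking one level per study as in real cross-study
  data; 5% core genes with log-effect magnitude ~1.5 (sd 0.3) and random
  sign; noise sd 0.4. These were chosen once as a realistic regime in which
  batch effects dominate the condition signal, and the per-study replicate
  split (the source studies' exact split is not published) uses 4–5 per
  condition.
* **One master seed** drives every draw; identical configurations are
  bit-identical.

What the generator does *not* emulate: count-level sampling noise
(log-normal, not negative-binomial — the pipeline consumes TPM-scale values
and all of its equations operate on log ratios, so a model with exactly
controlled log-scale moments is the right testbed), transcript-level
quantification uncertainty, correlated genes within pathways, and
library-size artifacts beyond a per-sample scale factor. Passing tests on
this generator therefore validate the statistical machinery, not the
upstream quantification of real data.

## Problem sizes used in the packaged analyses

The packaged checks run the meta-analysis recovery at 2,000 genes x 34
samples over 20 seeds, PVCA recovery at 1,000 genes over 20 seeds, and the
Monte-Carlo null at 200 draws of 60-gene subsets; these sizes give
Monte-Carlo errors comfortably below the tolerances being asserted while
keeping a full run in a few minutes on one core. The same code paths scale
to transcriptome-sized inputs unchanged (PVCA cost is dominated by one
$n_{\text{samples}}^2$ eigen-decomposition per draw).

## Known limitations

* The DL estimator with $k = 4$ studies estimates $\tau^2$ from 3 degrees
  of freedom; it is noisy, and the random-effects model at small $k$ is
  known to be liberal. The conservative $v_i = \mathrm{SE}^2 n_i$ variance
  convention and the BY correction push in the opposite direction.
* Per-factor independent REML fits double-count variance shared between
  confounded factors before renormalization; confounded factors are
  reported, not dropped, because study-nested design variables are the
  object of interest here. Interpret individual husbandry-factor fractions
  as "up to", not "exactly".
* The per-study normal approximation is liberal at very small replicate
  counts (see above); within-study DEG lists should be treated as
  candidate lists, with inference deferred to the meta-analysis.
* `kendall_matrix()` is quadratic in genes per sample pair; for large
  matrices compute it on the most variable genes (the pipeline driver
  does so by default).
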