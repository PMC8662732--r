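---
title: "Methods: association weight matrices and PCIT co-association networks"
author: "awmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association weight matrices and PCIT co-association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awmnet)
```

## The analysis model

The pipeline targets populations measured for many correlated phenotypes —
the motivating setting is a commercial pig line phenotyped for 30
immunological, haematological and stress traits — where single-trait GWAS
at genome-wide significance misses most of the architecture. Each trait is
analysed under the standard animal-model decomposition

$$ y_{ijk} = sex_j + b_k + u_i + s_{li}\,a_l + e_{ijk}, \qquad
   u \sim N(0,\, G\,\sigma_u^2),\; e \sim N(0,\, I\,\sigma_e^2) $$

with a two-level sex effect, a batch effect ($b_k$; phagocytosis-type
traits use a finer 12-level laboratory batch, two per rearing batch), an
infinitesimal polygenic effect $u$ whose covariance is the genomic
relationship matrix $G$, the candidate SNP dosage $s_{li} \in \{0,1,2\}$
and its allele substitution effect $a_l$. Assumptions worth stating: a
single additive random effect (no dominance or epistasis), relatedness
fully captured by $G$ (no explicit pedigree/litter term), and per-trait
optional natural-log transforms for right-skewed measurements.

**GRM.** `buildGRM()` uses the allele-frequency-standardized
cross-product estimator with the dedicated diagonal form,
$G_{ij} = m^{-1}\sum_k (x_{ik}-2p_k)(x_{jk}-2p_k)/(2p_kq_k)$ and
$G_{ii} = 1 + m^{-1}\sum_k (x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2)/(2p_kq_k)$,
with $p_k$ the counted-allele sample frequency and missing dosages
mean-imputed per SNP. Monomorphic SNPs are an error by design — they must
be removed by QC first.

**REML.** With one random effect the restricted likelihood profiles
exactly over $h^2 = \sigma_u^2/(\sigma_u^2+\sigma_e^2)$: after one
eigendecomposition $G = U\Lambda U'$, rotated observations are independent
with variances $h^2\lambda_i + (1-h^2)$ (up to the total variance, which
profiles out in closed form). `remlH2()` scans a 41-point grid over
$h^2 \in [10^{-6}, 1-10^{-6}]$ and refines the bracketing interval with
`optimize()` (tolerance $10^{-9}$), so the global optimum of the
one-dimensional profile is found without AI-REML iterations. The standard
error comes from the numerical curvature of the profile restricted
log-likelihood at the optimum (central differences, step $10^{-4}$);
boundary optima are flagged and get `NA` standard errors. Degenerate
traits (zero residual variance) are an error, never a silent estimate.

**Association scan.** `mlmAssoc()` is EMMAX/P3D-style: variance
components are estimated once per trait under the no-SNP model and the
implied covariance $V = \hat\sigma_u^2 G + \hat\sigma_e^2 I$ is held
fixed while every SNP is tested by generalized least squares in the
eigenbasis; the Wald statistic $(a_l/se)^2$ is referred to $\chi^2_1$.
This is the standard desk-scale choice (exact per-SNP REML would be ~40k
times slower and changes estimates negligibly at these sample sizes). No
leave-one-chromosome-out correction is applied: the model as stated uses
one whole-panel GRM, which slightly deflates signal at causal SNPs
(proximal contamination) but keeps the null calibrated — the test suite
verifies a 4–6% empirical type-I rate at nominal 5% and Kolmogorov–Smirnov
uniformity of null p-values.

## From GWAS to the association weight matrix

SNP selection is deliberately **nominal**: the AWM literature trades
stringency for information, so the key-phenotype rule is $p < 0.05$
(strict) and the pleiotropy rule is association with $\ge 3$ of the
traits at the same threshold (the key trait counts among the three; with
30 quasi-independent traits a null SNP passes the pleiotropy rule with
probability $\approx 0.19$, so roughly a fifth of the panel merges in by
construction — matching the proportions such studies report). Multiple-
testing correction is intentionally absent at this stage; genome-wide
Bonferroni thresholds belong in reporting, not in AWM selection.

Selected SNPs are annotated to genes whose span (GFF3 `gene` features,
1-based closed; BED converted on ingest) extended by a symmetric ±5 kb
window contains the SNP position, boundaries inclusive, strand ignored. A
SNP may annotate to several genes; unannotated SNPs are dropped with a
count. "Coding region" is interpreted as the annotated gene span, not
CDS-only, so intronic SNPs annotate to their gene.

The AWM cell for (gene, trait) is the **signed t-value** ($\beta/se$) of
the gene's representative SNP — t-values rather than raw effects because
the traits live on wildly different scales (counts, percentages, mg/ml) —
and columns are standardized to mean 0, unit sample variance. The
representative SNP per gene is the one associated with the most traits,
ties broken by smaller key-trait p-value, then smaller genomic position
(the source methodology never states this rule; the tie chain is ours and
deterministic). Column standardization is the default; row z-scoring is
not applied (the row correlations used downstream are location/scale
invariant per row anyway).

Trait relationships are the Pearson correlations between AWM columns,
clustered agglomeratively on distance $1-r$ with **average linkage** —
a convention choice, stated here because the source methodology does not
fix it — and serialized as Newick via `ape`.

## PCIT

`pcit()` reconstructs the Partial Correlation and Information Theory
filter from its published description. For every ordered trio $(x,y,z)$
the three first-order partial correlations are computed; the trio
tolerance is the mean of the three $|partial/direct|$ ratios (absolute
values, matching the reference implementation); edge $(x,y)$ is rejected
by $z$ iff $|r_{xy}| \le \varepsilon |r_{xz}|$ **and**
$|r_{xy}| \le \varepsilon |r_{yz}|$; an edge is significant iff no third
node rejects it. Numerical conventions, all tested:

* trios with any $|direct| < 10^{-12}$ or a non-positive partial
  denominator (collinear pairs, $|r| = 1$) are skipped — an undefined
  tolerance cannot support a rejection;
* an exactly zero correlation is never an edge (no association exists to
  keep), so an all-zero matrix yields an empty network;
* the fast path loops over the conditioning node and evaluates all pairs
  against it with vectorized matrix algebra ($O(n)$ passes of $O(n^2)$),
  and is exactly — not approximately — equal to the literal triple loop
  `pcitBruteforce()`, which the suite checks by exhaustive edge-set
  equality on dozens of random instances;
* the $O(n^3)$ scan refuses $n > 5000$ unless the guard is raised
  explicitly.

The network keeps isolated nodes (reported, not silently dropped), weights
edges by the direct correlation, and flags regulators by case-insensitive
symbol match against a user-supplied census; the pipeline never hard-codes
gene symbols. Topology statistics use the mean local clustering
coefficient with degree-< 2 nodes contributing 0 (the common
network-analyzer convention; an exclusion variant is a flag) and mean BFS
path length over connected pairs only, with the disconnected-pair count
reported separately rather than averaged as infinity.

## Regulator trios and key regulators

A regulator's target set is its network neighbourhood (other regulators
included, itself excluded). `rankTrios()` enumerates all $\binom{R}{3}$
trios and scores each by **unique coverage**: the number of distinct
non-member genes adjacent to at least one member. Ties break toward lower
redundancy (non-member genes reached by ≥ 2 members), then the
lexicographic member triple. "Unique interactions" could alternatively
mean the union of incident edges; that reading is available as
`countMode = "edges"` and both are reported, because the source reports a
trio table without defining the statistic.

`selectKeyRegulators()` realizes "maximum number of genes with minimum
overlapping" as greedy maximum coverage: repeatedly pick the regulator
adding the most uncovered genes (ties → larger total target set →
lexicographic), stopping early on zero gain so every retained pick has a
strictly positive marginal gain. Greedy is the standard tractable
realization and carries the usual $(1-1/e)$ guarantee, which the suite
verifies against exhaustive search on small instances; an exhaustive mode
exists for ≤ 25 regulators.

## The synthetic study generator

No genotype/phenotype data are deposited for the motivating study, so the
generator inverts the analysis model with known ground truth. What it
emulates, and the defaults (all `simConfig()` fields):

* **Population**: 432 individuals in full-sib litters (22 sires, 132
  dams — one litter per dam), built in two tiers: founder haplotypes per
  chromosome (pool of 24), parental gametes copying founder segments with
  a per-SNP template-switch probability of 0.10 (this sets LD decay), and
  offspring gametes recombining the parental pair at 0.005 per SNP.
  Litter mates share about half their genome, which is what carries the
  heritability information at a few hundred individuals — the per-trait
  REML standard errors this produces (~0.06–0.09 at n = 432-scale panels)
  match what such designs report.
* **Panel**: 68,516 SNPs on 18 autosomes (~50 kb spacing), allele
  frequencies uniform on (0.01, 0.5); planted QC failures — the low-MAF
  tail, 5% of SNPs with 20% missingness on top of 2% missing completely
  at random, and 30% unmapped SNPs — leave ~42k SNPs after QC at the
  default thresholds.
* **Genes**: 30 kb spans (the mammalian average) anchored on distinct
  mapped SNPs; module genes' anchors are the planted causal SNPs, so
  every causal SNP is recoverable by the ±5 kb annotation rule by
  construction.
* **Architecture**: co-effect modules with one latent trait-loading
  vector each; a member gene's causal effect vector across traits is
  $\sqrt{\rho}\,\lambda_k + \sqrt{1-\rho}\,\epsilon$ with $\rho = 0.8$,
  so within-module effect profiles correlate near 0.8 — the structure
  PCIT is supposed to find. Each module carries one designated hub
  regulator plus `hubExtraTargets` extra wired genes, planting
  regulator-like connectivity. Cross-module loadings can be
  orthogonalized (`simulateModuleProfiles(orthogonal = TRUE)`) to realise
  the "background ≈ 0" planted condition exactly.
* **Traits**: genetic value = `causalFraction` (default 0.5) causal +
  the rest polygenic, the polygenic draw having covariance proportional
  to the realised GRM; components are empirically standardized so the
  realised narrow-sense $h^2$ equals the per-trait target. Defaults are
  the 30-trait panel with moderate heritabilities (0.08–0.6); sex and
  batch effects are drawn at SD 0.25 trait-SD units. Missingness in
  genotypes is MCAR — no informative-missingness mechanism is modelled
  because none is described for the motivating data.

What the generator does **not** emulate, hence what passing tests do not
show about real data: genotyping error and allele-calling artifacts,
ascertainment bias of array SNPs, selection/inbreeding beyond two
generations, X-linked dosage, non-Gaussian trait distributions (no
log-normal or count noise), environmental correlation between litter
mates beyond the batch factor, and real gene-density heterogeneity.
Fixture I/O (PLINK `.ped/.map/.raw`, phenotype TSV, GFF3, census text,
truth JSON) round-trips losslessly through the package readers.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen once as the package's own study sizes: REML parameter recovery at
n = 600 / m = 3,000 (20 trait replicates per $h^2 \in \{0.3, 0.5,
0.7\}$ on a fixed panel); null-scan calibration pooled over ≥ 2,000
SNP tests and 5 simulated studies; the subset-heritability validation as
20 replicate studies of 300 × 2,000 with 20 random iterations each; the
planted-module PCIT check at 3 modules × (20 + 15) genes × 30 traits over
10 seeds; and the acceptance run at 300 × 6,000 × 30 with five modules,
2,110 genes and the full 100-iteration validation. Random-subset draws,
trait replicates and pipeline stages all derive their streams from one
root seed, and `runPipeline()` manifests are bit-identical across reruns
under a fixed seed.

Known limitations: the EMMAX approximation understates per-SNP evidence
slightly when a SNP explains a large variance share; h² standard errors
from profile curvature are asymptotic and degrade near boundaries (flagged
rather than reported); PCIT's trio rule has no error-rate interpretation —
it is a deterministic information filter, and no permutation FDR is
attached to edges (deliberately, matching the cited method); and greedy
key-regulator selection is optimal only up to the $(1-1/e)$ factor.
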