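---
title: "Methods: epistasis networks and the dyadicity of gene categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epistasis networks and the dyadicity of gene categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senet)
```

## The model

The package implements a two-stage analysis of case-control genotype data.

**Stage 1 — the statistical epistasis network.** For SNPs $A$, $B$ and a
binary phenotype $C$, all variables treated as categorical (genotypes as
minor-allele counts 0/1/2), the pairwise interaction score is the
information gain

$$IG(A;B;C) = I(A,B;C) - I(A;C) - I(B;C),$$

computed with plug-in (maximum-likelihood) entropies in base-2 logarithms,
where $(A,B)$ is the joint variable over the up-to-nine observed genotype
combinations. $IG$ is symmetric in $A$ and $B$, equals the full $H(C)$ for
a deterministic XOR phenotype of two fair loci, and is negative when the
two SNPs are redundant; negative values are retained and simply fall below
any positive edge threshold. SNP pairs with $IG$ strictly greater than the
threshold become edges; vertices are the edge-incident SNPs.

**Stage 2 — gene collapse and category statistics.** A SNP$\to$gene map
collapses the SNP network: genes are linked if any cross-gene SNP pair is
linked, within-gene SNP edges become self-loops, and parallel gene edges
merge (multiplicity kept as an edge attribute). For a binary gene category
with $n_1$ member genes in the $N$-vertex network, edges between distinct
vertices ($M$ of them) are classified by endpoint membership into (1-1),
(1-0), (0-0) dyads, and

$$D = \frac{m_{11}}{\bar m_{11}}, \quad H = \frac{m_{10}}{\bar m_{10}},
\quad \bar m_{11} = \binom{n_1}{2} p, \quad \bar m_{10} = n_1 (N - n_1) p,
\quad p = \frac{2M}{N(N-1)}.$$

The expectations are exact for uniformly random placement of the $n_1$
labels on any fixed graph, which is also the permutation null: labels are
shuffled with $n_1$ fixed, and $p$-values are the plain fraction of
replicates whose statistic is $\ge$ the observed one. A category can be
simultaneously dyadic and heterophilic when its genes are
well-interconnected hubs.

## Conventions that the arithmetic forces

* **Self-loops are excluded from $M$ and from all dyad counts.** A
  self-loop has one endpoint and cannot be classified by a pair of
  endpoint values, and the closed-form expectations are sums over distinct
  vertex pairs. On the reference 185-gene network shape with 174 edges
  including one self-loop, every published-scale expectation in the test
  suite is consistent only with $M = 173$; we verified this by
  recomputation before freezing the convention. Self-loops likewise do not
  join components and add nothing to neighbor counts, so that network's
  mean neighbor count is $2 \cdot 173 / 185 = 1.87$.
* **Degenerate categories report missing, not errors.** $D$ is undefined
  for $n_1 < 2$ and $H$ for $n_1 \in \{0, N\}$; both are returned as `NA`
  with `NA` $p$-values. $m_{11} = 0$ with $n_1 \ge 2$ gives $D = 0$ (and
  $p_D = 1$, since every permutation ties or exceeds zero).
* **$p$-value convention.** Plain fraction with ties counting toward
  significance, no $+1$ correction; the smallest reportable $p$ is
  $1/\mathrm{n\_perms}$. Each category draws from its own pre-seeded
  permutation stream (streams derived from the master seed by position),
  so per-category results are reproducible regardless of evaluation order,
  and $D$ and $H$ are tested on one shared stream per category. Whether to
  share one stream across categories was genuinely open; per-category
  streams match the fact that category analyses are mutually independent.
* **Strict edge inequality.** An IG value exactly at the threshold does
  not form an edge ("stronger than" the threshold).
* **Mode imputation tie-break.** Missing genotypes take the SNP's most
  frequent genotype; ties go to the lowest genotype code, for determinism.

## Threshold selection

The edge threshold is chosen by grid search against phenotype-permuted
nulls: for each candidate threshold the real network's giant-component
size is compared with its distribution over networks rebuilt from
label-shuffled phenotypes (case/control counts fixed), and the threshold
maximizing the $z$-score is selected. The degree-distribution contrast is
exposed in the diagnostics rather than folded into the selection
statistic: one scalar ("most distinguishing giant component") keeps the
choice transparent and monotone along the grid. Grid points whose null
variance degenerates (typically the extreme upper tail, where null
networks are empty) are skipped with a warning. The default grid is 50
evenly spaced quantiles of the top decile of the observed IG distribution
— data-adaptive, since IG scales with sample size and allele frequencies.
An analytic null for IG would be an alternative route to a threshold; the
permutation contrast was chosen because it makes no distributional
assumptions and directly operationalizes "more connected than expected".

## What the synthetic generators emulate

`generate_genotypes()` draws independent biallelic SNPs under
Hardy-Weinberg proportions with per-SNP MAF uniform on a configurable
interval (default 0.05–0.5), missing calls injected uniformly at random,
and a default shape of 1422 SNPs by 491 cases / 791 controls — the scale
of a candidate-gene case-control panel. Epistatic signal is planted
through 3×3 two-locus penetrance models:

* **xor** — risk depends on the parity of the summed minor-allele counts.
  At MAF 0.5 the parity of a Hardy-Weinberg genotype is a fair coin, so
  each locus alone is exactly independent of the phenotype: the canonical
  purely epistatic model, and the property the IG score targets.
* **threshold** — risk jumps when the combined dosage reaches 3; has both
  marginal and interaction effects.
* **multiplicative** — risk scales as $(1+\mathrm{effect})^{ab}$.

With planted pairs, each sample's disease weight is the mean penetrance
across pairs and exactly `n_cases` cases are drawn by weighted sampling
without replacement. This keeps class counts exact and leaves every
non-planted SNP phenotype-independent by construction; the cost is that
even a 0/1 penetrance does not make the phenotype deterministic (cases
are a draw from the high-risk stratum), so planted-pair IG approaches but
does not reach $H(C)$. `plant_epistatic_pair()` offers the complementary
behaviour — Bernoulli draws straight from the penetrance table, with
random class counts.

`generate_attributed_network()` plants dyadic or heterophilic label
structure by rejection-weighted edge sampling: all vertex pairs are
sampled without replacement with weight `strength` on 1-1 (respectively
1-0) pairs. This inflates the favoured dyad count by roughly the strength
factor in sparse graphs and exactly recovers uniform placement at
`strength = 1`, where the replicate means of $D$ and $H$ are 1 by the
closed-form expectations.

**What the generators do not emulate:** linkage disequilibrium between
SNPs, population stratification, genotyping batch effects, realistic gene
sizes or GO-term hierarchy (categories are uniform random subsets; real
GO terms are nested and correlated). Passing tests therefore demonstrate
the correctness and calibration of the statistics, not robustness to
confounding structure in real panels.

## Problem sizes and numerical choices

The all-pairs IG computation is expressed as nine indicator-matrix
cross-products per phenotype class, so the full $\binom{p}{2}$ score
matrix for the default 1422-SNP shape is a few dense matrix products
(about a second) rather than a million-iteration loop; a 50-SNP dataset
scores in milliseconds. The test suite and examples use 10–50 SNPs with a
few hundred to a few thousand samples, 100–1000 label permutations per
category, and 5–20 phenotype permutations per threshold grid point;
publication-grade category $p$-values use $10^5$ permutations
(configurable, `n_perms`). Entropies use the $0 \log 0 = 0$ convention;
mutual information is clamped at zero (it is analytically non-negative;
only rounding can push it below), while `information_gain()` is left
unclamped because genuine redundancy is informative. Equality of the
package's vectorized paths with brute-force reference loops is asserted
to $10^{-12}$ in the tests.

## Known limitations

* The plug-in entropy estimator is biased upward for sparse cells; with
  nine joint genotype cells and small samples, IG values are inflated for
  rare-allele pairs. The permutation null shares the bias, which is why
  thresholding is calibrated by permutation rather than by an absolute
  scale.
* Phenotype permutations for threshold selection recompute all pairwise
  scores per replicate, so selection cost is linear in `n_perms` times
  the all-pairs cost; for large panels choose the grid first on a subset
  or fix the threshold explicitly.
* Dyad expectations condition only on $(N, M, n_1)$, not on the degree
  sequence; a category concentrated on hubs can be significantly dyadic
  and heterophilic at once. This is a property of the statistic, not a
  flaw, but it means $D$ and $H$ should be read together.
* Gene categories are treated independently with no multiple-testing
  adjustment, matching the reference methodology; with hundreds of
  overlapping categories, interpret marginal $p$-values accordingly.
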