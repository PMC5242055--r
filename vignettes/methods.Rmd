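---
title: "Scoring genes and finding network modules from correlated significance tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genes and finding network modules from correlated significance tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmodules)
```

## The problem

Multi-level functional genomics experiments produce per-locus effect sizes
and p-values from several assays at once: differential expression per gene,
differential DNA methylation or hydroxymethylation per CpG, ChIP-seq peaks
delimiting regulatory intervals. Each track alone is often underpowered, yet
coincident signals at the same gene are strong evidence that something real
is happening there. `sigmodules` turns this intuition into a score: it
aggregates locus-level p-values within gene-anchored genomic contexts
(promoter, gene body, linked enhancer intervals), combines the contexts into
one significance value per gene, and then looks for connected subnetworks of
an interaction network that concentrate high-scoring genes.

Two statistical obstacles shape the design:

1. **Dependence.** Methylation signal is strongly correlated over short
   genomic distances, so the p-values inside one promoter are far from
   independent. Naive Stouffer or Fisher combination then anti-conservatively
   overstates significance.
2. **Aggregate-size bias.** Sums of folded Z-scores grow with the number of
   loci combined, so large gene bodies would dominate small promoters for
   purely geometric reasons.

Both are handled empirically — by Monte-Carlo estimation of the dependence
and by rank-based correction of the size bias — rather than by positing an
analytic joint distribution for the combined statistic.

## The procedure, stage by stage

### Contexts and locus association

A context couples an interval rule (promoter window, gene body, or an
external BED of intervals linked to the nearest TSS) with the score track
it draws from, a context weight $w_{\cdot j}$, a directionality coefficient
$B_{\cdot j} \in \{-1, 0, +1\}$, and a locus weighting scheme. Coordinates
are 0-based half-open throughout (BED convention); tracks declared 1-based
are shifted on load. The promoter default is 1000 bp upstream / 500 bp
downstream of the TSS and the enhancer-linking default is a 50 kb maximum
TSS distance; neither has a canonical literature value, so both are exposed
in the configuration rather than hard-coded.

### Distance-decay correlation and whitening

Within each (track, context) pair, the spatial dependence is estimated from
the data themselves: for every locus with $p \le 0.05$, the distance to its
nearest upstream and downstream neighbor is recorded together with the
folded Z-scores $Z = \Phi^{-1}(1 - p/2)$. Distances are cut into up to 500
quantile bins — quantile rather than equal-width, so the heavily populated
short distances get bins as narrow as a single basepair, where correlation
is strongest — and each bin's correlation is the mean Pearson correlation
over 500 within-bin resamples. Bins with fewer than 3 pairs carry
correlation 0 and are flagged unpopulated. Negative bin means are retained;
nothing downstream requires nonnegative correlation.

For an interval with loci at known positions, the profile lookup yields a
correlation matrix $\Sigma$ (diagonal 1, nearest-bin-center lookup
off-diagonal). Because bin lookups do not guarantee positive definiteness,
a failed Cholesky triggers a repair: eigenvalues clipped at $10^{-6}$,
matrix reconstructed, diagonal renormalized to 1, iterated until the
smallest eigenvalue clears the floor.

Decorrelation is Cholesky whitening. Writing $\Sigma = L L^{\top}$ with
$L$ lower triangular, the adjusted scores are $Z^{*} = L^{-1} Z$, computed
by forward substitution — never by explicit inversion. The triangular
convention matters: solving against the *upper* factor of
$\Sigma = U^{\top} U$ does **not** decorrelate (for two loci at
$\rho = 0.6$ it leaves residual correlation of about $-0.18$ and distorts
both variances), whereas the lower-factor solve gives exactly unit
variance and zero correlation for Gaussian inputs. The package therefore
solves $L Z^{*} = Z$; the whitening property is verified by simulation in
the test suite, and the variance of the downstream Stouffer aggregate is
restored to 1 from 3.4 at $\rho = 0.6$, $N = 5$.

### Aggregation and size adjustment

The interval aggregate is the weighted Stouffer statistic
$R_{ij} = \sum_k w_{ijk} Z^{*}_{ijk} / \sqrt{\sum_k w_{ijk}^2}$. Locus
weights are either uniform or a TSS-distance decay $2^{-d/h}$. The
default half-life is $h = 5000$ bp — the scale of a typical gene — so the
decay tilts evidence toward the TSS without effectively truncating gene
bodies (a 1 kb half-life would down-weight the far end of a 5 kb body by
$2^{-5}$ and change a fifth of the body-context directions). With this
default, uniform and decayed weighting give final scores with
$R^2 > 0.9$, so the weighting is a convenience, not a load-bearing
assumption.

Because the $Z$ are folded (nonnegative), $R_{ij}$ drifts upward with the
number of loci $N_{ij}$. The correction is rank-based: scores are
stratified into 10 quantile strata of $N_{ij}$ (strata under 5 scores are
merged with a neighbor), and each observed score is compared to 100 random
same-size samples drawn with replacement from its stratum. Each sample
contributes the proportion of sampled scores at or above the observation —
ties count half, and an add-one floor keeps the proportion strictly
positive so downstream logarithms stay finite — and the mean proportion
over samples is the adjusted p-value. On null data this removes the
locus-count trend of $-\log p$ to an OLS slope below $0.002$ per locus
while leaving the within-stratum ranking intact. The rank resolution is
limited by stratum size (about $1/(m+1)$ with $m$ scores per stratum), so
very small studies compress extreme signals; at genome scale this is
immaterial.

An interval's effect direction is the sign of
$\sum_k w_k \,\mathrm{sign}(e_k)\, Z_k$ over its locus effects $e_k$ —
loci with stronger evidence pull harder — with exact ties logged and
resolved to $+1$.

### Cross-context normalization

Adjusted p-value distributions still differ slightly across contexts, and
the heavier-tailed context would dominate gene scores. Two monotone,
rank-preserving rescalings are available: a logit rescale (default), which
standardizes each context's logits to the pooled mean and standard
deviation across all contexts, and a Box-Cox variant that finds the
likelihood-maximizing power transform of $-\log p$ on a $\lambda$ grid over
$[-2, 2]$ in steps of 0.01 before standardizing. Pooled moments make the
operation symmetric in the contexts and idempotent; "iterative
optimization" of the power parameter is realized as a grid-search MLE,
which is deterministic and trivially reproducible.

### Gene scores and the bootstrap null

Per gene, present contexts are Stouffer-combined once more:
$S_i = \sum_j w_{\cdot j}\, s_{ij}\, z_{ij} / \sqrt{\sum_j w_{\cdot j}^2}$
with $z_{ij} = \Phi^{-1}(1 - \bar p_{ij}/2)$ and sign
$s_{ij} = d_{ij} B_{\cdot j}$, where $d_{ij}$ is the interval direction.
$B_{\cdot j} = -1$ encodes the classic promoter-methylation /
expression anticorrelation: concordant evidence (expression down, promoter
methylation up) adds, discordant evidence cancels. $B_{\cdot j} = 0$
declares ignorance — such contexts contribute magnitude only, which is the
appropriate setting for hydroxymethylation or enhancer methylation where
no sign convention is established. Genes missing a context are scored from
what they have; only genes with no data at all are set aside (and
reported).

Significance is empirical: each context's signed contributions are pooled
across genes, and a gene's null statistics are rebuilt `n_boot = 1000`
times (configurable) by drawing independently from each pooled context and
recombining with the same weights. This exchangeability null preserves
every context's marginal distribution and nothing else. The combined
p-value is $(\#\{|S^{null}| \ge |S_i|\} + 1)/(B + 1)$; genes sharing a
context pattern share one cached null sample. The final score is Fisher's
$G_i = -2\log p_i$, $\chi^2_2$ under the null. Calibration tests use
$B = 20000$ so that the Monte-Carlo error of the shared null ECDF is small
against the Kolmogorov-Smirnov tolerance being tested.

### Modules

Gene scores are overlaid on an interaction network (largest connected
component; unscored nodes kept with score 0 and flagged). Spin-glass
community detection runs at resolution $\gamma = 0.5$ with edge weights
$1 + (\tilde G_a + \tilde G_b)/2$, where $\tilde G$ is the Fisher score
normalized by its maximum — a positive, bounded coupling of node scores
into the objective; the coupling lives in one function and can be swapped.
Since simulated annealing is stochastic, the partition is re-run
(3 restarts by default) and the solution maximizing the
Reichardt-Bornholdt objective at the same $\gamma$ is kept; single runs
settle in pair-merged local optima often enough to matter on small
networks. Communities outside the 8-100 gene window are discarded after
oversized ones get one recursive re-split.

Module significance is Fisher's method over member genes' combined
p-values: $\chi^2 = -2\sum_g \log p_g$ with $2k$ degrees of freedom.
Unscored members contribute $\log 1 = 0$ — a module can legitimately
implicate genes with no direct evidence. Modules are ranked by p-value,
ties by mean score then identifier.

As a single-subnetwork alternative, a greedy maximum-weight connected
subgraph heuristic grows from the best node with node weights
$G_i - \text{offset}$ (offset = background quantile of the scores),
attaching the positive node with the best weight-minus-path-penalty over a
node-weighted shortest path while the total increases. The exact
branch-and-cut formulation needs an integer-programming solver and is out
of scope; on exhaustive 8-node benchmarks the greedy reaches at least 80%
of the true optimum in over 90% of instances.

## What the generator emulates — and what it does not

The synthetic generator tiles genes along synthetic chromosomes, places
5-15 promoter and 10-40 gene-body loci per gene, and draws locus Z-scores
from a spatial model (independent, exponential decay with a 1 kb length
scale — the scale over which methylation autocorrelation is commonly
observed — or equicorrelated blocks). Planted genes receive a Z shift of
+3 with a coherent repression signature: expression down, promoter
methylation up, gene-body methylation down, with effect signs matching the
signature 90% of the time. The coherence is deliberate: under the reduced
model's directionality ($B = +1$ expression, $-1$ promoter, $+1$ body),
same-sign planting would cancel the promoter term against expression and
halve the planted signal.

The planted-partition network deserves a note. The planted genes form a
block with internal edge probability 0.3; the remaining genes are dealt
into background blocks of 40 at the same internal density, with 0.005
between blocks. Early designs left the background as one unstructured
sparse cloud, and community recovery failed — not because of the solver,
but because the generalized-modularity optimum at $\gamma = 0.5$ genuinely
absorbs singly-connected background nodes into the planted community and
merges block pairs whenever Poisson fluctuations of cross-block edge
counts exceed the between-block penalty $\gamma S_a S_b / 2W$. The chosen
defaults put the graph firmly in the detectable regime (penalty ≈ 10
versus cross-edge fluctuations of ~4 ± 2), which is what makes "Jaccard
≥ 0.8 against the planted truth" a well-posed benchmark rather than a
solver lottery.

The generator does **not** emulate platform artifacts (array probe design,
tagging-assay coverage bias), chromosome-scale covariates (CpG islands,
replication timing), hub structure of real interactomes, or correlated
nulls between contexts. Passing the calibration and recovery tests
therefore demonstrates that the machinery is statistically sound under its
own assumptions, not that any particular biological dataset satisfies
those assumptions.

## Numerical choices

* p-values are floored at $10^{-16}$ before the normal quantile transform
  (a p of exactly 0 warns); the Box-Cox path floors $-\log p$ at
  $10^{-12}$.
* All triangular systems are solved by substitution; matrices are never
  inverted.
* Positive-definite repair clips eigenvalues at $10^{-6}$ and renormalizes
  the diagonal, iterating until the floor holds.
* Every stochastic stage takes a seed derived from the single run seed by
  hashing the stage name, so adding a stage never perturbs the streams of
  earlier ones, and two runs with the same configuration and seed are
  byte-identical.
* Direction ties and empty intervals are logged, never silently dropped;
  genes without data appear in a report, not in the score table.

## Problem sizes used by the shipped tests

The test suite exercises the full pipeline at 2000 genes × 3 contexts
(null calibration), decorrelation at $10^4$ intervals of 5 loci,
size-adjustment at $10^4$ scores with 1-200 loci, profile recovery at
$10^4$ neighbor pairs, module recovery at 20 seeds of a 300-node network
with a planted 20-gene community, and greedy-subnetwork quality against
exhaustive enumeration on 100 8-node graphs. These sizes were chosen as
the smallest at which the Monte-Carlo error of each check is comfortably
inside its tolerance.

## Known limitations

* The quantile-permutation adjustment is rank-based, so its p-value
  resolution is bounded by stratum size; studies with a few hundred genes
  compress very strong signals (the bootstrap and module stages remain
  rank-correct).
* The spin-glass stage requires a connected network and is quadratic-ish
  in practice; networks of $10^4$+ nodes will want the greedy subnetwork
  route or a pre-partition.
* The greedy subnetwork heuristic carries no optimality guarantee; its
  80%-of-optimum behavior is an empirical benchmark on small graphs.
* Alternative locus-level combiners (Sidak, Fisher, binomial) bypass the
  decorrelation machinery and are offered for sensitivity analysis only;
  the decorrelated Stouffer route is the tested default.
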