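# sigmodules

Integrate gene expression with one or more epigenomic significance tracks
(differential DNA methylation, hydroxymethylation, ChIP-seq derived
intervals) into a single score per gene, and find modules of an
interaction network that concentrate high-scoring genes.

Who this is for: analysts holding several per-locus differential results
over the same samples — expression per gene, methylation per CpG — who
want one defensible per-gene significance instead of ad hoc intersections
of thresholded hit lists, plus network modules ranked by that
significance.

## The model

For gene *i* and genomic context *j* (promoter, gene body, enhancer
intervals, expression), the locus p-values overlapping the context
interval are folded to Z-scores, *Z* = Φ⁻¹(1 − *p*/2), decorrelated
against an empirically estimated distance-decay correlation matrix
Σ = *LL*ᵀ by the triangular solve *Z\** = *L*⁻¹*Z*, and combined with the
weighted Stouffer statistic

&nbsp;&nbsp;&nbsp;&nbsp;*R*ᵢⱼ = Σₖ *w*ᵢⱼₖ *Z\**ᵢⱼₖ / √(Σₖ *w*²ᵢⱼₖ).

A quantile-permutation step converts *R*ᵢⱼ to an adjusted p-value free of
the bias that grows with the number of loci combined; a monotone logit
rescale puts all contexts on a common scale. Per gene, contexts are
Stouffer-combined once more with researcher-chosen weights *w*.ⱼ and
directionality coefficients *B*.ⱼ ∈ {−1, 0, +1} (e.g. promoter
methylation opposing expression), significance comes from a bootstrap
exchangeability null, and the final score is Fisher's
*G*ᵢ = −2 ln *p*ᵢ.

Scores are overlaid on an interaction network; modules come from
spin-glass community detection (resolution 0.5, 8–100 genes,
score-coupled edge weights, best of several annealing restarts) or a
greedy maximum-weight connected subgraph heuristic, each reported with
the Fisher/χ² module significance −2 Σ ln *p*<sub>g</sub> on 2*k* degrees
of freedom.

Inputs are plain text: a gene BED, per-locus tracks
(`chrom position effect pvalue`), a gene-level expression table, optional
interval BEDs, and a two-column edge list. A synthetic-data generator
produces complete studies with planted signal for calibration and
benchmarking.

## Worked example

Simulate a 300-gene study with 20 planted genes (expression down,
promoter methylation up, gene-body methylation down, Z shift 3) and a
planted network community, then run the full pipeline:

```r
library(sigmodules)

cfg <- sim_config(n_genes = 300, n_planted = 20, effect_shift = 3, seed = 42)
man <- simulate_study(cfg, "study_inputs")

res <- run_pipeline(sim_run_config(man, "study_results", seed = 42))

head(res$gene_scores[order(-res$gene_scores$fisher_score),
                     c("gene_id", "statistic", "combined_p", "fisher_score")])
```

```
    gene_id statistic  combined_p fisher_score
113   G0113 -3.424883 0.000999001     13.81751
177   G0177 -3.960611 0.000999001     13.81751
206   G0206 -4.288212 0.000999001     13.81751
226   G0226 -3.998434 0.000999001     13.81751
275   G0275 -4.015246 0.000999001     13.81751
112   G0112 -3.035215 0.004995005     10.59863
```

The top genes hit the bootstrap resolution floor 1/(*n*<sub>boot</sub>+1)
= 1/1001, i.e. a Fisher score of −2 ln(1/1001) ≈ 13.8; their negative
statistics are the coherent repression signature (expression down with
promoter methylation up counts as concordant evidence under
*B*<sub>promoter</sub> = −1). All six are planted genes.

```r
head(res$module_tables$summary, 3)
```

```
  module_id  k      chi2 df      p_value mean_score
1       M03 20 188.32716 40 4.172753e-21   9.416358
2       M05 40  66.42011 80 8.616230e-01   1.660503
3       M08 39  63.60436 78 8.805970e-01   1.630881
```

The top module (p ≈ 4·10⁻²¹) is exactly the 20-gene planted community —
the background blocks of the interaction network are topological
communities too, but only the planted one carries significance.
`compare_context_scores(res$context_scores, "expression",
"promoter_meth")` reports per-gene paired scores and a direction
concordance rate, and every table is also written under
`study_results/`.

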