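# uvbloop

Analysis of loop-design two-color spotted microarray time courses that
compare the UVB stress response of two cell lines — the design used to
profile an SV40-transformed human fibroblast against its untransformed
counterpart after a single UVB dose, with RNA sampled at 4, 8, 16 and 24 h
together with matched mock-irradiated controls.

The package is aimed at analysts working with classical two-channel cDNA
array data (or teaching from it): 8 RNA samples hybridized pairwise on 10
arrays in a connected loop, no common reference channel.

## What it computes

1. **Normalization.** Per-spot `M = log2(Cy5/Cy3)` and
   `A = (log2 Cy5 + log2 Cy3)/2`; pin-wise (print-tip) lowess removes the
   intensity-dependent trend of M on A within each print-tip group.
2. **Log-linear ANOVA on the loop.** Per gene,
   `M_a = s[cy5(a)] − s[cy3(a)] + d + ε` over arrays `a`, where `s` are
   sample effects (sum-to-zero) and `d` a gene-specific dye term. Estimated
   by minimum-norm least squares; per-time-point UV-vs-control contrasts are
   tested with `F = ĉ² / var(ĉ)` on 1 df, against a residual variance pooled
   across genes.
3. **DE calls.** A gene is UVB-regulated at a time point iff fold change
   > 1.5 **and** Bonferroni-corrected p < 0.05; the union over time points
   gives each line's regulated set, tabulated per line and across lines.
4. **Clustering.** k-means (k = 6, best of 1000 restarts) on the raw 4-point
   log2FC patterns, with per-cluster mean profiles and up/down labels.
5. **Discrepancy statistic.** For every union-regulated gene, the Pearson
   correlation of its 4-point pattern between the two lines; a null
   distribution is built by randomly re-pairing genes across lines (100
   random bijections, correlations pooled). Genes with `r < −SD(null)` are
   the *most discrepant genes*; genes with `r > +SD(null)` are tallied as
   concordant.
6. **Enrichment.** A local EASE score — the one-tailed hypergeometric tail
   `P(X ≥ k−1)` after removing one gene from the group-term overlap — over
   GMT gene sets, with the "> 5 group genes in the term and score < 0.05"
   significance rule.

A synthetic-data generator (`truth_config()`, `simulate_paired_experiment()`)
produces two-line studies with planted DE genes, archetype time courses,
between-line discordant genes, dye/array/print-tip biases and spot noise, so
every stage can be scored against known truth.

## Worked example

```r
library(uvbloop)

cfg <- pipeline_config(
  truth = truth_config(n_genes = 6000, n_de_per_line = 965, n_discordant = 15),
  kmeans_restarts = 200, seed = 11)
report <- run_pipeline(cfg)
print(report)
```

```
UVB loop-design study report (lineA vs lineB)

                                lineA lineB Union
             Significant at 4 h   540   602   648
             Significant at 8 h   788   752   852
            Significant at 16 h   780   755   819
            Significant at 24 h   656   669   696
 Significant at >=1 time-points   966   965   966

Random-matching null: 100 iterations x 966 genes
  pooled mean 0.000676 , sd 0.6967
Most discrepant genes (r < -0.6967): 15 of 966 candidates; 908 concordant (r > +sd)
   gene          r
 g00009 -0.9958908
 g00008 -0.9907997
 ...
```

Reading this: 965 genes were planted as UVB-regulated in each line and the
dual criterion recovered essentially all of them (one extra false call makes
966); the per-time rows count genes passing both criteria at that time. The
random re-pairing of genes gives a null SD of 0.70 for this pattern pool, so
genes anti-correlated beyond −0.70 between the lines are flagged — here
exactly the 15 planted discordant genes, while 908 of 966 candidates are
concordant beyond +SD. `write_study_report(report, "out/")` writes every
table as TSV.

A thin command-line front end is in `inst/scripts/run_study.R`
(`simulate` and `run-all` subcommands).

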