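---
title: "Loop-design two-color analysis of paired UVB time courses"
author: "uvbloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop-design two-color analysis of paired UVB time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvbloop)
```

# The experiment this package models

Two fibroblast lines — in the motivating study an SV40-transformed line and
its untransformed parent — are irradiated with a single UVB dose and
harvested at 4, 8, 16 and 24 h, each with a matched mock-irradiated control.
For each line the 8 RNA samples are co-hybridized pairwise on 10 two-color
spotted arrays arranged in a *loop design*: samples are nodes, arrays are
edges, and the graph is connected, so every pairwise contrast is estimable
without a common reference channel. Each spot yields two intensities (Cy3,
Cy5) from which the log-ratio `M` and mean log-intensity `A` are formed.

The scientific questions are: which genes does UVB regulate in each line
(and when); what time-course shapes do they follow; where do the two lines
*disagree*; and which functions are over-represented in each regulated
group.

# The model and its stages

## Pin-wise lowess normalization

Spotted arrays show print-tip-dependent, intensity-dependent bias in `M`.
`printtip_lowess_normalize()` fits a lowess curve of `M` on `A` within each
(array, print-tip) group (`limma::loessFit`, span 0.4 by default) and
subtracts it. The span and the minimal group size (10 spots; smaller groups
fall back to a whole-array fit with a warning) are not biologically
motivated constants, just conventional smoothing choices; both are
arguments.

Lowess normalization assumes the bulk of spots in any intensity window are
unchanged genes. It is *not* exactly idempotent: a second pass refits local
noise averages of order noise/sqrt(window), and spots at the intensity
extremes of a tip group can move noticeably because a local fit is
boundary-dominated there. The test suite asserts approximate idempotence on
the bulk of spots rather than a machine-precision identity, which no local
smoother satisfies.

## The per-gene log-linear loop model

For one gene, the normalized log-ratio on array `a` is modelled as

    M_a = s[cy5(a)] − s[cy3(a)] + d + ε_a,

where `s` is a vector of sample effects and `d` a gene-specific dye term
(every `M` is Cy5 − Cy3, so a gene's dye bias enters each array
identically). Only differences of sample effects are meaningful;
`fit_gene_model()` computes the minimum-norm least-squares solution via the
SVD pseudo-inverse, which is the sum-to-zero-constrained representative.
Genes whose available arrays do not connect the sample graph are flagged
inestimable and skipped. The fit is algebraically the estimable core of the
classical global two-color ANOVA: the gene-wise ratio-scale formulation
yields identical contrasts at a fraction of the cost.

The UV-vs-control contrast at time `t` is tested with
`F = ĉ² / (v · σ²)` on 1 numerator df, where `v = c'(Z'Z)⁺c`. For the
default 10-array design each gene has only 2 residual df, and an F(1, 2)
p-value cannot reach Bonferroni-level thresholds no matter how large the
effect; global two-color ANOVA implementations share error variance across
genes. `contrast_test()` therefore defaults to a residual variance pooled
over all estimable genes (df summed, here about 2 per gene times the number
of genes), with `var = "genewise"` available for designs with real
replication. This is a deliberate design choice: with per-gene variance the
Bonferroni dual criterion would be vacuous on this design.

## The dual DE criterion and the union set

`call_de_genes()` flags a gene at a time point iff the model-estimated fold
change exceeds 1.5 *and* the Bonferroni-adjusted p (raw p times the number
of clones tested at that time point) is below 0.05. Fold change is measured
on the model contrast, not on raw ratio means, so both criteria refer to
the same estimate. Multiplicity is corrected within each time point; the
union over time points ("significant at ≥ 1 time points") is reported
without additional cross-time correction, matching how such tables are
conventionally presented. Clone-level tests can be collapsed to gene-level
unions through an optional clone-to-gene map.

## Clustering the regulated patterns

`cluster_patterns()` runs Euclidean k-means on the raw 4-point log2FC
vectors — unstandardized, so magnitude and direction drive the groups and
the up/down split of cluster profiles is meaningful. The conventional
"k = 6 with 1,000 iterations" budget is read as a restart budget: 1000
random initializations, each run to convergence, best total within-SS kept.
Both knobs are exposed (`restarts`, `max_iter`), and the per-restart SS
vector is returned so the best-of-restarts property is checkable.
`stats::kmeans` performs each restart. Ties and empty clusters are handled
by the underlying algorithm; if the input has fewer distinct patterns than
k, the effective k is reduced with a warning.

## The random-matching discrepancy statistic

For every candidate gene (by default the across-line union of regulated
genes) the Pearson correlation `r` of its 4-point pattern between the two
lines measures agreement. To calibrate what "low" means for the pattern
pool at hand, `random_match_null()` repeatedly draws a uniform random
bijection between the line-A and line-B genes (self-matches allowed, as
nothing forbids them), computes all matched correlations, and pools them
across 100 iterations. The pooled SD — not the mean of per-iteration SDs,
though both are returned — sets the threshold: `select_discrepant()` takes
genes with `r < −SD` strictly, and tallies `r > +SD` as concordant.

Two analytic facts anchor this procedure. For 4-point iid Gaussian
patterns the null correlation density is proportional to
`(1 − r²)^((n−4)/2)`, which at n = 4 is *flat*: Uniform(−1, 1), SD
`1/sqrt(3) ≈ 0.577`. The test suite verifies the estimator reproduces this.
For structured pools (patterns clustered into archetype shapes) the null is
strongly bimodal and its SD depends on the pool; on the simulated default
study it lands near 0.70, and on real fibroblast data this statistic is of
the same order (≈ 0.52 was reported for the motivating comparison).

Genes with zero-variance patterns have no defined correlation; they are
excluded from both the matching and the selection and counted in the
output, since silently coercing them would bias the SD.

## EASE-score enrichment

`ease_score(k, K, n, N)` is the one-tailed hypergeometric tail probability
`P(X ≥ k − 1)` — the standard Fisher tail after removing one gene from the
group-term overlap. It is conservative (always at least the unmodified
Fisher p) and renders single-gene overlaps unremarkable (score 1).
`enrich_terms()` applies it to every term with at least one hit and flags
terms with strictly more than 5 group genes and a score below 0.05;
no further multiple-testing correction is applied across terms, matching
the conventional use of this score. The background universe defaults to
all genes on the platform (an argument, since genome-wide backgrounds are
also in use). Annotations are read from GMT files.

# The synthetic-data generator

`truth_config()` + `simulate_paired_experiment()` generate a paired study
with known truth. Channel log2 intensities are

    baseline(gene) + sample×gene effect + array effect
      + dye×gene effect (Cy5 only) + print-tip curvature ± + noise,

exponentiated base 2. Treated-minus-control sample effects equal the
planted 4-point log2FC pattern exactly, so noise-free recovery is testable
to machine precision. The print-tip curvature is a zero-mean (per tip)
quadratic in spot intensity split between the channels, so it biases `M`
but never the per-tip mean. Dye-by-gene effects are drawn once per gene and
reused across arrays, the standard gene-specific dye-bias model.

Defaults, chosen once to represent a realistic study of this kind:

| parameter | default | meaning |
|---|---|---|
| `noise_sd` | 0.15 | sd of the spot log-ratio noise (each channel gets `noise_sd/sqrt(2)`); replicate-spot M noise of 0.1–0.2 is typical of good-quality spotted arrays |
| `dye_bias_sd` | 0.10 | gene-specific dye effect |
| `array_effect_sd` | 0.20 | per-array intensity shift (cancels in M) |
| `printtip_curvature_amplitude` | 0.30 | max M curvature per tip |
| `pattern_jitter_sd` | 0.30 | per-gene shape scatter around the archetype |
| `min_pattern_sd` | 0.50 | floor on within-pattern sd of planted DE genes |
| `concordant_target_r` / `discordant_target_r` | 0.9 / −0.95 | exact between-line pattern correlations of planted genes |

`noise_sd` is defined on the log-ratio scale deliberately: it is the scale
on which array noise is usually quoted and the scale on which the model
operates. Six archetype shapes (early/late/sustained, up and down) with
per-gene amplitudes in 0.7–1.5 define the planted time courses; jitter is
redrawn until the pattern's within-vector sd reaches `min_pattern_sd`. The
floor reflects that genes passing a 1.5-fold filter vary over the time
course; it also means the simulations do not exercise near-flat patterns,
whose 4-point correlations are intrinsically noise-dominated — a passing
planted-recovery test therefore says nothing about flat-profile genes in
real data, where such genes do occur and necessarily blur the discrepancy
statistic. Line-B patterns are constructed to hit the target correlation
*exactly* (a scaled combination of the line-A pattern and an orthogonal
complement), with the location sign-flipped for discordant genes so a gene
induced in one line is repressed in the other.

What the generator does **not** emulate: spatial artifacts beyond print-tip
curvature, intensity-dependent variance, saturation, missing/flagged spots,
clone redundancy, and cross-hybridization. Conclusions from passing tests
are about the algorithms, not about robustness to those phenomena.

# Numerical and design choices

- **Minimum-norm fits.** Rank deficiency is handled by SVD with the usual
  `max(dim) * max(d) * eps` tolerance; contrast estimability is checked by
  projecting the contrast onto the row space of the per-gene design.
- **Pooled vs gene-wise variance.** See above; pooled is the default and
  the only mode under which Bonferroni-level calls are reachable on the
  10-array design.
- **Strict thresholding.** The discrepancy rule uses strict `r < −SD`, and
  the enrichment size filter strict `k > 5`, as both rules are
  conventionally stated.
- **Determinism.** Every stochastic stage takes a seed; the pipeline
  derives per-stage seeds from one master seed and `run_pipeline()` output
  is byte-stable, which the tests verify file-by-file.
- **Problem sizes in the tests.** The acceptance-style tests run at the
  scale the methods are meant for: 6000-clone platforms with 965 planted
  candidates for discrepancy recovery (the published comparison's candidate
  count, at a realistic regulated fraction — lowess normalization assumes
  most genes are unchanged, so studies where most of the platform is DE are
  outside the method's operating range), 2000 genes for DE calibration and
  power, and an exhaustive sweep of all hypergeometric configurations with
  `N ≤ 200` for EASE exactness.

# Known limitations

- The per-time F test inherits the pooled-variance assumption of
  homoscedastic genes; strongly variance-heterogeneous platforms would
  call for moderated statistics instead.
- With only 4 time points, pattern correlations are coarse: the null SD is
  large (≈ 0.6–0.7 for structured pools) and only strong anti-correlation
  is detectable; the procedure finds *the most* discrepant genes, not all
  discrepant ones.
- GEO Series Matrix ingestion (`read_geo_series_matrix()`) parses the
  format but deliberately does not attempt to reconstruct any deposited
  study's preprocessing; mapping samples to design roles is the caller's
  responsibility.
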