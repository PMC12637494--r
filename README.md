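# mechanotec

Cells sense mechanical confinement and answer with coordinated, time-dependent
transcriptional programs that are tied to where their genes sit in the
three-dimensional genome. `mechanotec` implements the analysis chain that links
the two layers — temporal expression clustering on one side, Hi-C–derived
subcompartments, chromosome territories and radial nuclear positioning on the
other — together with a synthetic-data generator that plants every piece of
statistical structure the analyses assume, so that the whole chain is testable
against known ground truth without any sequencing data.

It is aimed at computational genomicists who want a small, fully inspectable
R implementation of these methods, either to analyse their own binned contact
maps and log fold-change tables or to study the statistical behaviour of the
procedures themselves.

## What is implemented

**Temporal expression clusters (TECs).** Genes carry a log2 fold-change
trajectory over four confinement timepoints (15 min, 1 h, 4 h, 24 h versus the
unconfined control). Trajectories are clustered with Ward-D2 agglomeration on
Euclidean distances, cut with an adaptive dendrogram pruner (a dynamic
tree-cut variant working on the merge structure alone, with a minimum cluster
size and a `deep_split` aggressiveness knob), and gated by silhouette width:
genes with s(i) = (b − a)/max(a, b) < 0.1 fall into TEC0, the
irregular/non-responsive class. Generic term aggregation (graph components
over a supplied semantic-similarity matrix) and hypergeometric gene-set
enrichment profile the resulting clusters.

**Subcompartments.** A simplified eight-state ranker: per chromosome, the
leading eigenvector of the Pearson correlation of the observed/expected
contact matrix gives a continuous openness score, discretized genome-wide
into equal-count octiles A3 > A2 > A1 > A0 > B0 > B1 > B2 > B3 (most open to
most repressed). Replicate tracks form a consensus (same label in ≥ 2 of 3
replicates), TSSs inherit their bin's label, and label changes are classified
as chromatin *opening*/*closing* on the rank order, with facultative
(A1–B1) gains and losses, plus Mbp-scale switch matrices.

**Hi-C matrix statistics.** ICE balancing (iterative correction to equal row
sums), exact multivariate-hypergeometric downsampling to matched totals,
distance-decay expected models, Poisson upper-tail significant-interaction
calling with BH control and log2 observed/expected filters (1.5 trans / 2.0
cis at FDR 0.01) plus ≥ 2-of-3 replicate consensus, insulation-score TAD
boundaries with ≥ 5-of-9 cross-sample consensus, and a simplified
negative-binomial Wald test (median-of-ratios size factors,
moment dispersion shrunk to the genome-wide mean) for coarse-bin
differential contacts.

**Beads-on-string models.** A compact Chrom3D-style Monte-Carlo embedder:
one spherical bead per consensus TAD, radius ∝ length^(1/3) scaled to a
nuclear occupancy of 0.15 in a 5 µm sphere, Metropolis optimization of chain
continuity, excluded volume, nuclear containment (a hard envelope) and
attraction constraints from consensus Hi-C interactions. Downstream:
largest-overlap bead annotation, pooled radial medians ± sd with pairwise
Wilcoxon rank-sum tests (Holm-adjusted), and per-bead median radial shifts
between conditions with a signed-rank test.

**Genome-wide reorganization.** Mean balanced interchromosomal contact
frequency per chromosome pair, a strictly decreasing transform to
dissimilarities, Kruskal nonmetric MDS (k = 2, isotonic regression +
Guttman updates), Procrustes comparison across conditions, homotypic (A/B)
and subtelomeric annotation of differential contacts, per-TEC overlap
proportions, and Fisher exact association tests (e.g. subcompartment
opening/closing versus up-/down-regulated TECs).

## Worked example

Planted trajectories in, temporal expression clusters out:

```r
library(mechanotec)

sim  <- sim_expression_lfc(genes_per_cluster = 200, n_irregular = 600, seed = 3)
tecs <- tec_cluster(sim$lfc, min_cluster_size = 50)
glance(tecs)
#> # A tibble: 1 × 4
#>   n_genes n_tecs tec0_fraction min_silhouette_assigned
#>     <int>  <int>         <dbl>                   <dbl>
#> 1    2000      7         0.375                   0.107

dplyr::filter(tec_profiles(sim$lfc, tecs), timepoint == "C4h")
#> # A tibble: 8 × 6
#>     tec timepoint    mean median    sd     n
#>   <int> <fct>       <dbl>  <dbl> <dbl> <int>
#> 1     0 C4h        0.0539  0.193 1.69    750
#> 2     1 C4h       -1.15   -1.13  0.344   209
#> 3     2 C4h        1.76    1.76  0.306   206
#> 4     3 C4h       -3.20   -3.18  0.352   205
#> 5     4 C4h       -2.47   -2.47  0.318   203
#> 6     5 C4h        3.20    3.19  0.330   203
#> 7     6 C4h        2.59    2.56  0.303   201
#> 8     7 C4h        2.54    2.30  0.901    23
```

2000 genes went in: seven planted trajectory classes of 200 plus 600
irregular genes. Six of the planted classes come back essentially intact
(n ≈ 200, per-timepoint means within sampling error of their archetypes —
compare `tec_archetypes()`), the silhouette gate collects the irregular
genes in TEC0 (750 genes, near-zero mean, large sd), and the
weakest-separated planted trajectory is largely absorbed into TEC0 at this
noise level — exactly the failure mode the gate is designed to make visible.

The full synthetic study — triplicate Hi-C in three conditions with planted
subcompartment switches coupled to the expression clusters — runs end to end
in seconds:

```r
study <- run_toy_study(seed = 1)
study$association$C15m$table
#>          up down
#> opening 302    0
#> closing  11  198
study$association$C15m$test
#> # A tibble: 1 × 4
#>   odds_ratio odds_ratio_mle         p or_defined
#>        <dbl>          <dbl>     <dbl> <lgl>
#> 1        Inf            Inf 1.22e-129 FALSE
```

Genes of upregulated clusters were planted in genome blocks that open after
15 minutes of confinement, downregulated clusters in blocks that close; the
recovered cross-table is almost perfectly concordant (an infinite sample
odds ratio is flagged rather than silently propagated), confirming that the
subcompartment calling, consensus, TSS mapping and switch classification
chain preserves the planted coupling.

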