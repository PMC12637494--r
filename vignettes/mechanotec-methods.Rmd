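---
title: "Models and methods behind mechanotec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mechanotec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanotec)
```

`mechanotec` analyses the interplay between temporal transcriptional
responses to mechanical confinement and 3D genome organization: clusters of
log fold-change trajectories (TECs), eight-state Hi-C subcompartments and
their switching, significant and differential chromatin contacts,
beads-on-string nuclear models with radial statistics, and interchromosomal
MDS. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where the methodology left room —
including what the synthetic-data generator does and does not emulate.

## The synthetic-data generator defines the study conditions

All statistical claims the test suite and the acceptance script make are
claims about *planted* structure:

* **Expression trajectories.** Seven archetypal log2 fold-change vectors
  over the contrasts C15m, C1h, C4h, C24h (each versus the unconfined
  control), in `tec_archetypes()`. Two rows are anchored to reported
  cluster means — the Wnt-associated class `(−0.851, 1.184, 0.443, 0.63)`
  and the cytokine class with an early dip of −1.574 followed by stable
  means above 3 — and the remaining five keep the observed qualitative
  shapes (classes 1, 3, 4 transiently up at 15 min and settling down by
  4 h; 2, 5, 6, 7 the mirror image). Their magnitudes were fixed once so
  that planted classes are mutually separated by at least ~2.3 log2 units,
  clearly more than the 4-dimensional member noise at `noise_sd = 0.3`;
  planted classes that overlapped at the noise scale would make "recovery"
  an ill-posed target. Irregular background genes are iid Gaussian with
  `irregular_sd = 2`, spanning the dynamic range of the responsive genes.
  A *smaller* spread would concentrate the background at the origin, where
  it forms a perfectly coherent cluster of its own — flat, non-responsive
  profiles are a legitimate expression class, not an "irregular" one —
  while a spread on the scale of the archetype cloud produces genes that
  fit no trajectory, which is what the TEC0 gate is meant to capture.
* **Contact maps.** Expected cis counts decay as a power law of bin
  distance, `cis_scale · d^(−γ)`; every pair is modulated by
  `1 + κ·s_ij` with the activity-similarity kernel
  `s_ij = 1 − |a_i − a_j|` (bounded in [0, 1], symmetric, unit diagonal)
  over planted per-bin openness `a ∈ [0, 1]`; trans pairs have constant
  base expectation. Planted pairs multiply the expectation by a fold in one
  condition, and the subtelomere helper places trans pairs in the terminal
  10 % of chromosomes, emulating the confinement-induced subtelomeric
  gains with partial reversal. Pixel noise is Poisson by default, or
  negative binomial (dispersion 0.05) for calibrating the differential
  test. Replicates are iid — no batch structure, coverage gradients,
  mappability artefacts or fragment-level biases, so passing tests show
  correctness of the inference chain, not robustness to real-data
  artefacts.
* **Bead clouds.** Isotropic directions with group-specific radial
  distributions (truncated Gaussians), used to validate the radial
  analytics independently of the Monte-Carlo embedder.

## TEC clustering

Trajectories are clustered by Ward-D2 (`hclust`, Euclidean distance — the
metric Ward's criterion presumes). The cut is an adaptive pruner on the
merge tree alone:

* The *trimmed height* of a branch is the height of the sub-branch still
  holding ≥ 90 % of its leaves. This is the branch-height statistic used
  everywhere; it ignores outliers chained loosely above a cluster core,
  which otherwise erase the height gap at real junctions.
* A node is a *significant split* if both children hold at least
  `min_cluster_size` leaves (default 100) and the mean of their trimmed
  heights is at most `α` times the node height. `deep_split ∈ {0..4}` maps
  to `α ∈ {0.52, 0.56, 0.60, 0.64, 0.68}`. The grid is calibrated for this
  ratio statistic: for Ward linkage on homogeneous data a balanced split
  satisfies `h_child ≈ sqrt(1/2)·h ≈ 0.71·h` (heights grow with the square
  root of cluster size), so the conservative end demands a gap far below
  the homogeneous baseline and the aggressive end approaches it. The
  published reference grid {0.64 … 0.95} belongs to a different
  normalization (0–1 cophenetic dissimilarities) and transfers poorly to
  raw Ward heights, where 0.64 is nearly always satisfied.
* Clusters are the trimmed cores of maximal gap-free branches that are
  tightly attached (trimmed height ≤ (α + 0.03) × attachment height);
  loosely attached diffuse branches — the irregular background — and small
  side branches are shed to label 0.

Silhouette widths are computed (package `cluster`) over genes with non-zero
labels on the same Euclidean distance, and the gate assigns every gene with
width < 0.1 (and every gene the cut left unassigned) to TEC0; remaining
clusters are renumbered by decreasing size. The defaults
(`min_cluster_size = 100`, `deep_split = 0`, threshold 0.1) mirror the
reference analysis workflow; the planted-recovery checks run at minimum
size 50 because the toy study uses 200-gene classes.

Whether silhouettes are computed before or after renumbering is immaterial
— the gate is order-invariant — and the package computes them before.
TEC numbers are size-ranked labels, not identities: correspondence to any
particular published cluster is by profile shape.

Term aggregation is deliberately generic: the package consumes a term×term
similarity matrix (it does not compute semantic similarity or touch the GO
DAG), keeps terms with ≥ 10 member genes, the top 50 by adjusted p, links
pairs with similarity ≥ 0.3, and reports connected components with the most
significant member as representative (ties broken by term id).
Over-representation uses the exact hypergeometric upper tail with BH
adjustment across all cluster–set cells.

## Subcompartments

The eight-state caller is intentionally simpler than a nested-hierarchy
tool: per chromosome, observed/expected (expected = per-diagonal mean
within the chromosome), Pearson correlation of O/E columns, leading
eigenvector, sign-oriented so its correlation with a user-supplied activity
covariate is positive (planted activity in simulations; gene density is
the natural covariate on real data), and scaled to unit variance per
chromosome so scores are comparable genome-wide. Bins with zero coverage
are `NA`; all-zero or constant chromosomes yield `NA` with a warning.
Discretization is by equal-count octiles genome-wide (per-chromosome on
request via `per_chromosome = TRUE`; the genome-wide default keeps octiles
balanced on toy genomes), ties broken by bin order, `A3` for the highest
octile. The rank order A3 > A2 > A1 > A0 > B0 > B1 > B2 > B3 is a module
convention, motivated by the permissive-to-repressive gradient; the
facultative band is A1–B1.

Consensus requires the same label in ≥ 2 of 3 replicates, else `NA`.
Switches are classified on the rank order (toward A = opening) and by
entry/exit of the facultative band; switch matrices report Mbp with `NA`
bins excluded. TSS mapping uses 0-based half-open containment, so a TSS on
a bin boundary belongs to the right-hand bin.

## Hi-C statistics

* **ICE balancing** iterates `w ← w / sqrt(rowsum/mean)` until the maximum
  relative row-sum deviation is below `tol` (default 1e-5, cap 200
  iterations, non-convergence flagged); all-zero bins are masked. Weights
  are normalized to mean 1.
* **Downsampling** draws pixel counts without replacement (sequential
  conditional hypergeometric over the upper triangle), hitting the target
  total exactly and mirroring for symmetry.
* **Significant interactions** use a Poisson upper tail
  `P(X ≥ obs | μ = expected)` with BH over all tested pairs and a log2
  observed/expected filter — 1.5 for trans, 2.0 for cis, FDR 0.01 (log
  base 2 assumed where the reference workflow leaves the base unstated).
  The Poisson tail replaces a non-central hypergeometric test; at the
  planted effect sizes the log-ratio filter dominates the call set, which
  is why the simplification calibrates well (the null simulations in the
  acceptance suite bound the false-discovery proportion at 1 % FDR).
  Replicate consensus keeps pairs passing in ≥ 2 of 3 replicates.
* **Insulation boundaries**: mean balanced signal in the window×window
  square straddling each bin (window default 10 bins), log2-normalized by
  the chromosome mean (making boundaries scale-invariant); boundaries are
  local minima with prominence ≥ 0.1 log2 units. Cross-sample consensus
  clusters boundaries by single linkage within 1 bin and keeps positions
  supported by ≥ 5 of 9 samples (the fraction is kept when the sample
  count differs); the consensus segmentation feeds the bead models.
* **Differential contacts**: fine counts are aggregated to coarse bins
  (5 Mb in the reference setting; the toy study uses 2 Mb so that enough
  coarse pairs exist), and tested with a simplified negative-binomial Wald
  test on raw counts with median-of-ratios size factors. The per-pair
  method-of-moments dispersion (4 df at 3 vs 3) is shrunk toward the
  genome-wide mean with precision weight 0.2; the genome-wide target is
  the *untruncated* moment mean, which is nearly unbiased, while the
  truncated per-pair term is not. An equal-weight blend leaves so much
  estimation noise and truncation bias in the standard errors that a
  two-fold change at μ = 100 and dispersion 0.05 becomes nearly
  undetectable at 3 vs 3 even though the known-dispersion Wald test
  detects it — hence the precision-weighted blend, which restores null
  calibration (rejection ≈ 0.05 at p < 0.05) and power close to the
  oracle. This is still far simpler than an empirical-Bayes trend: with
  genuinely heterogeneous dispersions the strong shrinkage trades per-pair
  adaptivity for stability, which is the right trade at replicate-level
  sample sizes.

## Beads-on-string models

One bead per consensus TAD, one chain per chromosome, radius ∝ genomic
length^(1/3), scaled so the summed bead volume is `occupancy` (default
0.15) of a 5 µm nuclear sphere — the radius default follows common
practice for these models and matches the 3–4 µm radial medians the
analyses operate on. Chains start as touching-step random walks inside the
nucleus (rejection sampling). The Metropolis optimizer uses single-bead
Gaussian displacements (σ = 0.2 µm) with geometric cooling
(T ← 0.999·T): squared penalties for chain continuity (adjacent beads at
touching distance), excluded volume between non-adjacent beads, and
attraction constraints pulled to touching; the nuclear envelope is *hard*
— proposals leaving the sphere are rejected outright — so containment of
the initial configuration is invariant rather than approximately enforced.
The best-so-far configuration and its non-increasing loss trace are
returned; ensembles use consecutive derived seeds. Richer move sets
(rotations, band moves) and lamina/nucleolus landmarks are intentionally
absent; run lengths are configurable, with a few thousand steps sufficing
for the 30–40-bead toys in the test suite and 2×10^5 a reasonable default
scale for larger chains.

Radial statistics pool bead-center distances across all models per label
(per-model medians available via `per_model = TRUE`; pooling is the
default reading of the reference workflow and the flag covers the other),
report median ± sd, and test all label pairs with Wilcoxon rank-sum
(exact below n = 25, normal approximation with continuity correction
otherwise) under Holm adjustment — Holm for pairwise families, BH
elsewhere, following the respective conventions. Per-bead shifts take the
across-model median distance per bead in each condition and test the
paired differences with a two-sided signed-rank test.

## Interchromosomal MDS and association tests

Chromosome-pair profiles average balanced trans pixels (zeros included).
Because contact frequencies must become dissimilarities before embedding
and the reference workflow does not state the transform, both `1/f`
(default) and shifted `−log f` are provided; zeros are replaced by half
the smallest positive frequency first. The nonmetric MDS is Kruskal's
algorithm: classical (Torgerson) initialization, isotonic regression of
configuration distances on dissimilarity ranks (`isoreg`, primary
approach to ties), Guttman-transform updates, termination when stress-1
improves by less than `tol` (default 1e-6) or fails to decrease — so the
accepted trace is non-increasing by construction. Cross-condition
comparisons use symmetric Procrustes (translation, rotation, reflection,
scale; package `vegan`), with the normalized reference returned so
per-chromosome displacements are computed in a consistent space.

Fisher tests report the sample odds ratio `ad/bc` (flagged when infinite
or undefined) alongside the conditional-MLE estimate, with the two-sided
point-probability p-value of `fisher.test`. The switching-versus-
regulation test crosses opening/closing at TSSs with membership in
up- versus down-regulated clusters (defaults 2, 5, 6, 7 up and 1, 3, 4
down at 4 h, matching the direction classes the archetypes encode);
stable genes are excluded. Subtelomeric annotation uses a 5 Mb absolute
window by default (fractions < 1 are interpreted relative to chromosome
length). Track-overlap matrices report intersected Mbp (features merged
first), per-row z-scores and log2 Mbp.

## The end-to-end toy study

`run_toy_study()` wires everything together on a genome of 8 × 8 Mb
chromosomes in 100 kb bins with 1 Mb activity blocks cycling through the
eight openness levels (each level once per chromosome, so genome-wide
octiles are balanced). Per chromosome, one near-closed block opens at
C15m and partially reverts at C4h, and one near-open block mirrors this
— the planted, partially reversible switch structure. Genes of the
up-classes are placed in opening blocks and down-classes in closing
blocks, so the opening/closing × up/down Fisher association has planted
odds ratio above 1; irregular genes land anywhere. Triplicate contact
maps per condition (κ = 2, Poisson, cis scale 250 by default) carry
additional subtelomeric trans gains among four chromosomes at C15m
(fold 6) that partially revert at C4h (fold 2.5). The pipeline then runs
every stage above and returns all intermediate objects next to the
planted truth.

Problem sizes throughout the tests and the acceptance script — 2 000
genes, 640-bin genomes, 2 000 coarse pairs, 20-seed Monte-Carlo toys,
ensembles of a handful of models — were chosen as the smallest scales at
which the planted effects are comfortably identifiable; they keep a full
run in the tens of seconds.

## Known limitations

* The subcompartment ranker is a single-eigenvector method: it recovers
  one openness axis and cannot represent nested or multi-axis compartment
  structure; exact octile agreement saturates around 0.85–0.9 on toys
  because within-level eigenvector noise never fully vanishes.
* The NB differential test has no dispersion trend and assumes a shared
  dispersion scale; the Poisson interaction test ignores overdispersion
  (conservativeness is absorbed by the log-ratio filter).
* The simulator plants iid replicate noise and piecewise-constant
  activity; none of the coverage, distance or batch artefacts of real
  Hi-C are modelled, so calibration results transfer to real data only to
  the extent those artefacts are corrected upstream.
* The embedder is a minimal Monte-Carlo scheme; its ensembles explore far
  less conformational space than dedicated tools and are meant for
  statistical plumbing (annotation, radial analytics), not structural
  inference.
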