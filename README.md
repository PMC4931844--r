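# crnet

Mutual-information network analysis of gene expression under graded
treatment, built for study designs like graded calorie restriction
(CR): a few hundred genes, a handful of ordered treatment levels, and
only 5–8 biological replicates per level. Correlation-based
co-expression networks miss non-monotone gene–gene relationships,
which are expected to become more common as a regulatory network
approaches a state shift. `crnet` therefore infers networks from
mutual information and compares them, level by level, against their
Spearman-correlation counterparts.

## What it computes

For each treatment level the pipeline performs a two-step inference:

1. **Pairwise dependency.** Expression values are discretized
   (equal-frequency, `B = ⌊√n⌋` bins by default) and mutual
   information is estimated for every gene pair with the Miller–Madow
   bias-corrected estimator,

   `Ĥ_MM = Ĥ_emp + (m̂ − 1) / (2n)`,  `Î(X;Y) = Ĥ_MM(X) + Ĥ_MM(Y) − Ĥ_MM(X,Y)`,

   in nats, with negative estimates clamped to zero. A parallel
   Spearman matrix maps `ρ` onto the same scale via `−½ log(1 − ρ²)`.

2. **ARACNE pruning.** For every gene triplet `(i, j, k)` the edge
   `(i, j)` is removed iff `w_ij < min(w_ik, w_jk) − ε` (data-processing
   inequality, single simultaneous pass against the original matrix;
   `ε = 0` is the canonical default, `ε ≈ 0.2` is recommended when the
   goal is module recovery at small n).

Each pruned network is then characterized by node strength
`s_i = Σ_j w_ij`, the Barrat weighted clustering coefficient,
hierarchy and scale-free diagnostics (log–log survival linearity plus
a maximum-likelihood power-law fit with a seeded KS bootstrap),
eigenvector centrality (dominant eigenpair of the adjacency, max
scaled to 1) with central-gene identification, and Louvain modularity
clustering with the weighted modularity coefficient

`Q = (1/2W) Σ_ij (w_ij − s_i s_j / 2W) δ(c_i, c_j)`.

Cross-level comparison tracks cluster flows (adjusted Rand index
between consecutive levels), per-gene centrality trends along the
gradient, and CMI-versus-correlation differences. An O-PLS-DA
classifier with permutation validation tests whether expression
predicts treatment level. A synthetic-data generator with planted
clusters, hubs, graded rewiring, graded state shift and U-shaped
dependencies provides ground truth for every stage.

## Worked example

```r
library(crnet)
library(SummarizedExperiment)

se  <- generateExpression(syntheticSpec(seed = 21))   # 408 genes, 37 samples
mm  <- buildMIM(se, treatment = "40CR")               # Miller-Madow MI matrix
net <- aracne(mm)                                     # DPI-pruned network
net
#> GeneNetwork (cmi): 408 genes, 62106 edges, DPI epsilon = 0

detectCommunities(net, seed = 21)
#> Partition (louvain): 408 genes in 4 clusters, Q = 0.3284

prof <- eigenvectorCentrality(net)
head(identifyCentralGenes(prof, tau = 0.9))
#> [1] "g0100" "g0108" "g0109" "g0112" "g0113" "g0333"

rep <- runPipeline(se, pipelineConfig(seed = 21))
rep@summaryTable[1:2, 1:4]
#>   treatment estimator modularity clusters
#> 1      12AL       cmi  0.6714842       10
#> 2      24AL       cmi  0.8232375       10
```

The modularity coefficient Q measures how much more edge weight falls
within clusters than expected at random (0 = no modular structure);
the cluster count and Q per treatment-by-estimator network form the
pipeline's headline comparison table. On synthetic studies the
correlation networks consistently show more, smaller clusters with
higher Q than the CMI networks — the two estimators genuinely measure
different structure.

A thin command-line wrapper with verbs `simulate`, `infer`,
`topology`, `communities`, `oplsda` and `run` is installed at
`inst/scripts/crnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/crnet.R", package="crnet"))')" \
    simulate --genes 408 --seed 1 --out-dir sim/
```

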