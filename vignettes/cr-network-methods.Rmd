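---
title: "Methods: mutual-information networks across graded treatments"
author: "crnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-information networks across graded treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnet)
```

## The problem

Graded calorie-restriction designs measure a few hundred candidate
genes (aging, inflammation, oxidative stress) in a handful of animals
per treatment level — typically six ordered levels with 5–8
replicates each. The scientific questions are network-level: does the
dependency structure among these genes reorganize along the gradient,
which genes are topologically central, and does a mutual-information
(MI) view of dependency see anything a rank-correlation view misses?
`crnet` implements the full analysis: per-level network inference,
topology characterization, community structure, centrality, and
cross-level and cross-estimator comparison, plus a classifier stage
and a synthetic-data generator that gives every step a ground truth.

## Dependency estimation

Expression values for one treatment level are discretized gene by
gene with a common number of bins `B` and pairwise MI is estimated
from the contingency tables with the Miller–Madow bias-corrected
plug-in estimator: the empirical entropy plus `(m − 1)/(2n)`, where
`m` counts non-empty cells. MI is reported in nats because the
correction keeps its simple form under natural logarithms. Negative
MI estimates (possible because the three corrections do not cancel)
are clamped to zero so that edge weights stay non-negative; the raw
value is available via `clamp = FALSE`.

Two estimator choices matter and are exposed as configuration:

* **Bins.** Default `B = max(2, ⌊√n⌋)` with equal-frequency binning —
  the customary heuristic for MI network inference at small n, and
  the only workable choice at n = 5–8 where it gives `B = 2`. The
  square-root rule should not be pushed to large n for *joint*
  estimation: at n = 5000 it creates `B² ≈ n` joint cells, a regime
  where the Miller–Madow correction substantially under-corrects the
  plug-in bias (the estimator overshoots a known bivariate-Gaussian
  MI by roughly a third). When an accurate *value* of MI matters, not
  just a ranking, cube-root binning (`B ≈ n^{1/3}`) keeps the median
  estimate within a few percent; the unit tests document both
  behaviours.
* **Scheme.** Equal-frequency (rank-based, ties broken by position)
  makes every gene's marginal near-uniform, so pairwise estimates are
  comparable across genes and invariant to monotone transforms of
  expression; equal-width is provided for completeness and degrades
  gracefully on constant genes.

The correlation counterpart ranks expression, computes Spearman's ρ,
and maps it onto the same nats scale via the Gaussian MI identity
`−½ log(1 − ρ²)`, so both estimators can be pruned and compared under
one rule. Perfect correlations map to infinity and are capped at the
largest finite similarity plus one, preserving rank order.

## Pruning

ARACNE removes the weakest edge of every triplet that violates the
data-processing inequality: edge `(i, j)` is marked iff
`w_ij < min(w_ik, w_jk) − ε`, all marks are evaluated against the
original matrix, and removals are applied in one simultaneous pass —
the operation is deterministic, order-independent, and idempotent.
Ties survive (strict inequality), and triplets containing a zero
similarity never trigger a removal.

`ε = 0` (the canonical DPI) is the default. It is worth understanding
what exact DPI does to a module driven by one latent factor: in the
noise-free limit, every within-module edge except those touching the
single best-correlated gene is removable, so a module's ideal pruned
form is a *star*. With estimation noise at n ≈ 100 the star's edges
are removed or retained near-randomly at the margin, fragmenting
modules into chains that modularity optimization then splits. A small
tolerance, `ε ≈ 0.2` nats relative to within-module MI of ~1 nat,
retains near-tied within-module edges while still removing
between-module edges whose DPI margin is large. This is the package's
recommended setting when the analysis goal is module recovery, and it
is what the community-recovery tests use; `ε` remains 0 wherever the
canonical rule is the object of study.

## Topology, centrality, communities

* **Strength** is the row sum of the pruned similarity matrix.
* **Clustering** uses Barrat's strength-normalized weighted
  coefficient (sum over ordered neighbour pairs of the mean incident
  weight on closed triangles, normalized by `s_i (k_i − 1)`); it
  reduces to the binary coefficient for unit weights and is zero for
  degree < 2. The geometric-mean alternative can be swapped in
  because the coefficient is isolated behind one function.
* **Hierarchy** is judged by the Spearman correlation of clustering
  coefficient against strength over nodes with degree ≥ 2: verdict
  "yes" iff ρ < 0 at p < 0.05, "inconclusive" when fewer than ten
  nodes qualify or the correlation is undefined.
* **Scale-freeness** combines two checks, and demands both: R² ≥ 0.9
  of the log–log survival regression over all positive strengths (the
  straight-line-on-a-log-log-plot criterion), and a bootstrap p ≥ 0.1
  for the KS distance of a continuous maximum-likelihood power-law
  fit with KS-minimizing lower cutoff. The semi-parametric bootstrap
  (100 seeded replicates; body resampled, tail simulated) re-selects
  the cutoff per replicate, and replicates are rounded to integers
  when the observed strengths are integers so that tie-induced KS
  inflation affects data and replicates alike — without this the test
  is anticonservative on unit-weight degree sequences.
* **Centrality** is the dominant eigenpair of the symmetric adjacency
  (all entries made non-negative per Perron–Frobenius, maximum scaled
  to 1). On a disconnected graph the component with the largest
  dominant eigenvalue is used and all other genes get 0, with a
  warning — the convention is visible rather than silent. Central
  genes are those with centrality ≥ τ (default 0.9); the threshold is
  a parameter because "the few genes with disproportionally large
  centrality" is not otherwise operational.
* **Communities** come from seeded weighted Louvain; the modularity
  coefficient `Q = (1/2W) Σ (w_ij − s_i s_j/2W) δ(c_i, c_j)` is
  computed by the package's own routine (igraph's implementation
  serves as an independent cross-check in the tests). The returned
  partition is guaranteed not to score below the one-cluster or
  all-singleton baselines.

## Classification stage

O-PLS-DA one-hot-encodes the class labels, autoscales the genes,
removes `nOrtho` components of X-variation orthogonal to the class
space (the orthogonal weight is the predictive loading minus its
projection onto the rank-truncated basis of `X'Y` — the truncation
matters, because centered one-hot Y has rank `classes − 1`), and fits
a NIPALS PLS2 model with two predictive components. `Xvar` is the
percent of scaled predictor variance captured by the predictive
components; validation permutes labels, refits everything, and
reports `p = (1 + #{Xvar_perm ≥ Xvar_obs})/(n_perm + 1)`, which can
never undercut `1/(n_perm + 1)`. With `nOrtho = 0` the fit reduces
exactly to PLS-DA. Defaults (1 orthogonal component, 2 predictive,
999 permutations) follow common chemometrics practice and are
configurable.

## The synthetic generator

Each planted cluster is driven by one standard-normal latent factor
per treatment level; factors share an exchangeable correlation
(default 0.3) through a global factor, because co-expression modules
in one tissue are never orthogonal — this also gives the
between-module dependence floor against which non-monotone pairs are
judged. A gene's log-expression is `loading × factor + noise`
(loadings U(0.6, 1), noise SD 0.3), exponentiated onto a positive
normalized-count-like scale. Four kinds of structure are planted, all
recorded in a truth object:

* **Hubs** (default: the first gene of each cluster) load on their
  own factor with multiplier 3 and on ring-neighbour factors with
  0.15. The multiplier makes the hub the best factor-aligned gene in
  its module, hence the centre of the module's pruned star and its
  centrality maximum; the cross-loading is kept below the noise floor
  deliberately — larger values add unaligned variance that makes the
  "hub" *less* aligned than ordinary members and destroys the very
  property it is meant to plant.
* **Non-monotone pairs.** A fraction (default 0.2) of each cluster's
  genes couple to the standardized *square* of the factor. Against
  linear cluster-mates they have population Spearman ρ = 0 but
  substantial MI — the planted analogue of relationships a
  correlation network cannot see.
* **Rewiring.** Per level, a seeded gene subset (fraction 0, 0.05,
  0.10, 0.15, 0.20, 0.30 by default along the six levels) is
  reassigned to a different cluster relative to the first level,
  mirroring graded cluster-membership change. No effect sizes exist
  to copy, so these are set for testability.
* **Graded treatment signal.** Cluster factor means drift linearly
  along the gradient (signed per-cluster magnitudes, default scale
  1.5) and a 10% gene subset carries an additional signed log-scale
  mean shift up to 1 — the state-shift and differential-expression
  analogues that give the classification stage something to detect.
  Neither changes within-level dependence, so network inference is
  unaffected.

What the generator does *not* emulate: count noise, library-size
effects, gene-specific dispersion, or any real mouse gene — passing
tests demonstrate correct recovery of planted structure under a
Gaussian-factor model, not performance on RNA-seq data. At the
study's own sample sizes (5–8 per level, B = 2 bins) MI estimates are
extremely noisy; the per-treatment networks are reported as the
design dictates, and the recoverability guarantees in the tests are
established at n = 100 per level, a size at which the estimator is
informative. Likewise, with 37 samples against the default graded
signal the permutation-validated Xvar is usually non-significant —
the test is honest rather than powerful at this n.

## Numerical choices and degenerate inputs

Constant genes: zero similarity with a warning (Spearman) or a single
occupied bin carrying zero information (MI). Constant clustering or
strength vectors make the hierarchy diagnostic "inconclusive" rather
than an error. Edgeless networks refuse centrality ("centrality
undefined") and community detection ("empty network"). All
stochastic steps — Louvain, bootstraps, permutations, simulation —
take explicit seeds and run on a local RNG stream that restores the
caller's state. Problem sizes used by the test-suite recovery runs
(60–100 genes, 100–200 samples, 20–50 replicates) were chosen as the
smallest at which the planted effects are comfortably detectable.

## Known limitations

The ε and τ conventions, the Barrat form of weighted clustering, and
the Louvain algorithm are each one defensible choice among several;
all are recorded in the objects they produce so alternatives can be
compared. The scale-free verdict inherits the low power of
goodness-of-fit testing at a few hundred nodes. Per-treatment
networks at n = 5–8 should be read as exploratory summaries, not
estimates with guarantees.
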