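---
title: "Ricci curvature analysis of functional connectivity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ricci curvature analysis of functional connectivity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Resting-state fMRI group studies commonly reduce each subject to a
functional connectivity network (FCN): nodes are atlas parcels (ROIs),
edges encode the Pearson correlation between the parcels' average BOLD
time series. Standard graph-theoretic measures (clustering, modularity,
efficiency, betweenness) summarize the topology of these networks;
discrete Ricci curvatures are geometry-inspired complements that quantify,
edge by edge, how neighbourhoods spread or overlap. `riccifc` implements
the full comparison pipeline — graph construction, curvature and standard
measures, multi-density group statistics, clinical-score correlation and
term-enrichment decoding — together with a synthetic cohort generator so
every stage is testable without imaging data.

# Graph construction

Each subject's symmetric, unit-diagonal correlation matrix is reduced to a
series of **binary** graphs over a grid of edge densities (default 0.02 to
0.50 in steps of 0.01, i.e. 49 graphs per subject):

1. the maximum spanning tree (MST) is built with Kruskal's algorithm over
   the off-diagonal correlations — this guarantees a connected backbone of
   $n-1$ edges;
2. the remaining edges are appended in decreasing order of their
   correlation value until the graph at density $d$ holds
   $\operatorname{round}(d\,n(n-1)/2)$ edges;
3. weights are then discarded.

The series is nested by construction, every member is connected, and all
subjects have identical edge counts at each density, which makes measures
directly comparable across subjects.

Numerical choices this construction leaves open in the literature, fixed
here:

* **Edge ranking** uses *signed* correlations in decreasing order (the
  literal reading of "decreasing order of correlation"); negative
  correlations therefore enter last. A `rank_by = "absolute"` switch is
  provided.
* **Tie-breaking** is lexicographic on the (i, j) node pair, applied
  identically in Kruskal and in thresholding, so results are
  platform-independent.
* **Edge-count rounding** is round-half-to-even (R's `round`), avoiding a
  directional bias across the grid.
* A density whose budget falls below $n-1$ cannot hold the MST; this is a
  configuration error that reports the minimum feasible density rather
  than a silently clamped graph.

# Curvatures

**Forman–Ricci curvature (FRC)** of an unweighted edge $e=(u,v)$ is the
combinatorial expression $F(e) = 4 - \deg u - \deg v$ (classical) or
$F^\#(e) = 4 - \deg u - \deg v + 3t(e)$ with $t(e)$ the number of
triangles through $e$ (augmented). The **augmented form is the default**:
in FCN applications FRC findings closely track clustering-coefficient
findings, which is only explicable if triangles enter the formula; the
classical form remains available.

**Ollivier–Ricci curvature (ORC)** of an edge is
$\kappa(u,v) = 1 - W_1(m_u, m_v)/d(u,v)$, where $m_x$ places mass $\alpha$
at $x$ and $(1-\alpha)/\deg x$ on each neighbour, $d$ is the hop-count
distance and $W_1$ the Wasserstein-1 distance. Default idleness is
$\alpha = 0$ (the non-lazy convention of the comparative literature the
study builds on; the value used by the original authors is not stated in
their main text, so it is configurable).

$W_1$ is solved **exactly** as a balanced transportation problem by
successive shortest augmenting paths on the bipartite supply/demand
network (`min_cost_transport()`). Supports are neighbourhoods (at most
max-degree + 1 points) and costs are integer hop counts, so the shortest
path labels are exact and the optimum is attained to machine precision; no
entropic approximation is involved. The test suite checks every edge of
every connected graph on up to 6 nodes against an independently written
two-phase simplex oracle (itself validated against values frozen from an
external LP solver during development), at tolerance 1e-9.

**Node curvature** is the sum of incident edge curvatures, so
$\sum_{\text{nodes}} \kappa_{\text{node}} = 2 \sum_{\text{edges}} \kappa_e$
exactly (the handshake identity, asserted in the tests).

# Standard measures

Average Watts–Strogatz clustering (degree-<2 nodes contribute 0),
Newman–Girvan modularity of the partition found by deterministic greedy
agglomeration (`igraph::cluster_fast_greedy`; the optimizer is
configurable, and reported modularity is optimizer-dependent), mean hop
count, mean betweenness
normalized by $(n-1)(n-2)/2$, global efficiency (mean inverse distance)
and average local efficiency over *open* neighbourhood subgraphs — the
dominant convention of the efficiency literature. All are delegated to
igraph and validated against closed forms and, for modularity and
betweenness, against exhaustive partition / path-enumeration oracles.

# Group statistics

Global measures are compared density-by-density with a two-tailed
two-sample t test (pooled variance by default, Welch via
`var_equal = FALSE`), followed by
Benjamini–Hochberg FDR at $\alpha = 0.05$ **across densities within each
measure**. Nodal measures are first collapsed to one number per node by
the trapezoidal AUC over the density axis, then tested per node with BH
FDR **across nodes within each measure**. These per-measure FDR families are a
design decision; pooling across measures as well would be stricter.

Partial correlation with covariates (age, gender encoded 0/1)
residualizes both variables on the covariates plus intercept and
correlates the residuals, with $df = n - k - 2$. Constant covariate
columns are dropped (they duplicate the intercept); other rank
deficiencies are errors. A variable exactly explained by the covariates
has residual zero, and the correlation is taken as 0 by convention.

# Decoding

Significant ROIs are partitioned by resting-state network; for each RSN
the frequency count of each associated term is compared against the
counts of 1000 (default) equal-size surrogate ROI sets drawn uniformly
without replacement from the whole atlas (configurable to the RSN's own
pool). The z-score is converted to a one-sided upper-tail normal p (the
procedure reports enrichment only), BH-adjusted across terms within the
RSN. With a degenerate null (zero surrogate sd) the p-value is
$1/(n_{\text{surrogates}}+1)$ if the observed count exceeds the mean, else
1 — a permutation-style floor that avoids infinite z while preserving
ordering. Surrogate count, pool and sidedness are all configurable and
logged, since published uses of this procedure vary in all three.

# The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` plants the statistical structure the analysis assumes:

* block-constant correlation targets (modules standing in for RSNs), with
  group "A" receiving an additive reduction of the within-block mean —
  the direction of the clinical effect the pipeline is meant to detect;
* subject-level Gaussian jitter on the off-diagonals, projected to the
  nearest valid correlation matrix (eigenvalue floor + diagonal
  renormalization), so every matrix is a legal Pearson matrix without
  rejection sampling;
* optionally, subjects realized as multivariate Gaussian time series
  whose sample correlation is the emitted FC matrix (matching the Pearson
  definition of FC);
* ages uniform on 7–58 years and ~15% female, mirroring the demographic
  ranges of the emulated cohort — cosmetic, for covariate plumbing;
* clinical scores linear in a designated nodal measure plus noise,
  available for group A only (severity scores exist only for the clinical
  group);
* a term table with planted enrichment in one RSN.

**Default parameter choices.** `within_block_mu = 0.30` and
`between_block_mu = 0.10` are typical within- versus between-network
Pearson FC magnitudes in parcellated resting-state data. This choice is
load-bearing: a *uniform additive* within-block reduction changes the
*binarized* topology only where the within- and between-block weight
distributions mix under noise. With a within/between gap of four noise
standard deviations (group B) the modules are cleanly segregated, at one
standard deviation (group A after a 0.15 reduction) they are not, so the
planted effect survives thresholding. Had the gap been, say, 0.5 against
noise 0.05, both groups would select essentially the same edge ranks and
produce exchangeable binary graphs — no effect size up to 0.15 could be
detected, not because the pipeline is insensitive but because the
binarization genuinely removes that contrast. `group_effect = 0.15` and
`noise_sd = 0.05` are the recovery conditions asserted in the acceptance
suite; `n_subjects_per_group = 50` gives the t tests conventional power
at these effect sizes.

**What a green test does not establish.** The generator draws i.i.d.
Gaussian jitter: no site effects, motion artifacts, hemodynamics,
distance-dependent noise, or heavy-tailed FC distributions. Recovery of a
planted block effect demonstrates the pipeline's statistical machinery,
not robustness to fMRI confounds — those are handled (or not) upstream of
this package's inputs.

**A known, deliberate property: curvature spillover.** Because every
subject's graph at density $d$ has exactly the same number of edges,
weakening one block's correlations displaces edges *into* the remaining
blocks. Per-node-normalized measures (clustering) stay localized: with an
effect confined to one block, all FDR-flagged clustering nodes fall in
that block. Node curvature, an unnormalized sum over incident edges, is
sensitive to this budget redistribution: in the same cohort roughly a
third of FRC-flagged nodes lie outside the affected block (mean spillover
|t| ≈ 1.3–2 versus ≈ 15 inside). This is a real property of MST +
fixed-sparsity binarization worth keeping in mind when interpreting
node-curvature maps, and it is why the localization test in the suite
uses nodal clustering.

# Degenerate inputs and numerical conventions

* FC matrices: symmetry tolerance 1e-12 in memory, 1e-8 from text files
  (absorbs decimal rounding), then symmetrized by averaging; diagonal
  forced to exactly 1; off-diagonal range checked before clamping
  floating-point overshoot.
* A density grid whose smallest budget equals $n-1$ produces trees for
  every subject, making clustering identically zero in both groups — the
  pooled t is then undefined and raised as an error, not silently skipped.
* Curvature values are reported at full precision; no rounding anywhere
  in the pipeline.
* All randomness (cohort, scores, term tables, surrogate draws) flows
  from one master seed via fixed-offset substreams, so every artifact is
  reproducible and subjects are independent.

# Limitations

* Weighted-graph curvature (general vertex/edge weights, curvature flow)
  is out of scope; the pipeline analyzes binarized networks only.
* ORC cost grows with degree (one exact transport solve per edge); on
  dense 200-node graphs FRC is orders of magnitude faster and serves as
  the computationally light surrogate.
* The modularity optimizer is greedy; reported modularity is a lower
  bound on the optimum (exactness is verified only on small fixtures
  against exhaustive partition enumeration).
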