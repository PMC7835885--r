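---
title: "Inferring physiological networks from biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring physiological networks from biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physionetr)
```

## The model and its assumptions

`physionetr` infers an undirected weighted network over the variables of a
subjects × variables biomarker table. The statistical model is
deliberately minimal: an edge asserts a significant *monotone* association
between two variables across subjects, nothing more. Three assumptions
drive the design:

1. **Biomarker marginals are asymmetric and leptokurtic.** Clinical
   variables (hormone levels, cell counts, enzyme activities) are rarely
   Gaussian. Every association is therefore measured with the Spearman
   rank correlation — the Pearson correlation of midrank-transformed
   values — which is invariant under monotone transformations, and the
   Shapiro–Wilk screen (`shapiro_screen()`) documents the non-normality
   that justifies the choice. It never modifies the data.
2. **Significance, not magnitude, defines the link set.** Each pairwise ρ
   is tested with the Student-*t* approximation
   *t* = ρ√((n−2)/(1−ρ²)), df = n−2, and an edge exists iff *p* < α.
   Raw p-values are thresholded, not FDR-adjusted: the threshold grid
   itself is the sensitivity analysis, and the type-I behaviour is
   verified empirically (the edge false-positive rate on independent null
   cohorts sits within three binomial standard errors of the nominal
   rate; see `test-acceptance.R`).
3. **Association strength matters after thresholding.** Surviving edges
   are weighted by ρ², giving positive weights in (0, 1] regardless of
   correlation sign; the signed ρ, the p-value, and the pairwise sample
   count are retained per edge.

Missing cells are handled pairwise: each pair uses its complete
observations and its own n in the t test. This matches a screening stage
that blanks individual implausible values rather than dropping subjects.

## Data processing

- **Normalization** (`normalize_median_range()`): x = (V − Me)/(Max − Min)
  per variable, centering on the median and scaling by the range —
  statistics appropriate for skewed, heavy-tailed distributions. Rank
  correlations are unaffected (asserted to 1e−12 in tests); normalization
  exists for display and cross-variable comparability. Constant variables
  are a hard error, since the map is undefined.
- **Outlier screen** (`rout_screen()`): a robust-fit, FDR-controlled
  screen applied per column. The location is the median; the robust scale
  (RSDR) is the 68.27th percentile of absolute residuals with an
  n/(n−1) small-sample correction; residuals become two-sided t-tail
  p-values and cells are flagged by Benjamini–Hochberg control at rate Q
  (default 0.01). Flagged values become missing cells — per-value
  discards, not subject deletion. The screen iterates to a fixed point,
  which makes it idempotent on its own output; columns with fewer than 10
  values or zero robust scale are skipped and reported.
- **Derived variables** (`derive_variables()`): the clinically standard
  derived panel (MAP, BMI, bioimpedance and leukocyte proportions,
  Castelli indices, HOMA-IR/HOMA-β, BUN, FEV1/FVC). Unit conventions are
  fixed explicitly: height in cm is converted to m for BMI, glucose in
  mg/dL is divided by 18.016 to mmol/L for the HOMA formulas (insulin in
  mIU/L). The fat-free-mass proportion is defined as 100·(Wt−BF)/Wt.
  Parents are never mutated; non-finite results (e.g. division by a zero
  leukocyte count) become missing cells with a report entry.

## Choosing the threshold

`threshold_scan()` rebuilds the network along a decreasing grid (default
0.05 … 1e−6, spanning the window where topology stabilizes) and records
the full metric panel at each α. Two empirical regularities motivate the
selection rule in `select_threshold()`: tightening α removes the weakest
links preferentially (mean removed weight ≤ mean retained weight, a
tested invariant), so density falls faster than strength; and
connectedness stays near 1 until some α below which the graph
fragments. The rule returns the smallest grid α whose connectedness is
still ≥ `min_connectedness` (default 0.95) — the most stringent
threshold that keeps the network whole. If no grid point qualifies the
largest α is returned with a warning rather than an error, so scans on
sparse data still complete.

## Topology metrics: conventions that matter

- **Path metrics are unweighted** (hop counts). Characteristic path
  length averages over *reachable* pairs only, so isolates and
  cross-component pairs do not inject infinities.
- **Krackhardt connectedness** is the fraction of node pairs joined by a
  path; **Krackhardt efficiency** is 1 − (surplus edges beyond a spanning
  structure)/(maximum possible surplus). Both are 1 on any tree; K4 has
  efficiency 0.
- **Barrat clustering**: the weighted local coefficient
  c_i = Σ (w_ij + w_ih) / (s_i (k_i − 1)), summed over unordered
  neighbour pairs (j, h) that close a triangle at i, aggregated two
  ways — T weights nodes by
  k_i(k_i−1) (the weighted analogue of global transitivity), CC is the
  plain mean. Nodes of degree < 2 are excluded from both. With unit
  weights both collapse exactly to their unweighted counterparts, which
  is the tested anchor.
- **Small-world indices**: SWI uses analytic baselines C_rand = k̄/n,
  L_rand = ln n / ln k̄ on the main component; smallworldness draws B
  (default 100) seeded Erdős–Rényi graphs with identical n and edge
  count and uses their mean transitivity and path length. Both require
  mean degree > 1.
- **Scale-free fitting index**: degrees are binned into 10 equal-width
  bins; log10 frequency is regressed on log10 mean bin degree by ordinary
  least squares. R² is reported unsigned, with the slope alongside so a
  decaying fit (slope < 0) can be distinguished. Regular graphs (fewer
  than 2 nonempty bins) are rejected rather than given a fake R².

## Centrality

Eigencentrality is the leading eigenvector of the ρ²-weighted adjacency,
computed by shifted power iteration to relative tolerance 1e−10 (the
shift by the maximum strength prevents oscillation on bipartite graphs)
and rescaled to max = 1; it is the radial, influence-type measure.
Flow betweenness is the medial, gatekeeping measure: the total pairwise
max-flow lost when a node is removed, with capacities equal to the edge
weights. Whether the source workflow used weighted or binarized
capacities is not documented; weighted is the default here for
consistency with the weighted graph, and the choice is an explicit
argument surface (binary capacities can be had by setting unit weights).
All-pairs max-flows use Gusfield flow-equivalent trees (n−1 max-flow
calls per graph instead of n²/2), verified edge-for-edge against direct
pairwise max-flow in the tests. Freeman centralization is the relative
form Σ(c_max − c_i)/((n−1)·c_max); note this gives (n−2)/(n−1), not 1,
for the degree vector of a star — the value 1 requires the theoretical
star-maximum denominator, a different normalization that is not used
here. Assortativity of a centrality is the Pearson correlation of
endpoint values over the edge list with both orientations counted.

## Communities

Louvain (greedy two-phase modularity optimization) and the two-level map
equation are the two clustering routes; both run through igraph's
optimizers, but the *reported* scores are always recomputed
independently: modularity by the package's own
Q = (1/2m)Σ(w_ij − s_i s_j/2m)δ(c_i,c_j), and the description length by
`map_equation()` (in bits, matching the codelength convention; the
variation of information is in nats). On an 8-node two-clique benchmark
the Louvain partition attains the exhaustive-search maximum over all
4140 partitions, and the map-equation partition attains the
exhaustive minimum — small enough to enumerate, which is why that graph
is the oracle. The Rand index is the headline agreement metric
(unadjusted, the common toolkit default); the adjusted Rand index is
used wherever chance correction matters, in particular for
planted-structure recovery. Resolution is fixed at 1; the seed shuffles
the node visiting order and is a mandatory part of a run configuration.
Cluster contraction keeps every inter-cluster edge individually
(multigraph), anchored at each cluster's strongest member, so the total
cross-cluster weight is conserved exactly.

## Permutation inference

CUG tests binarize the observed graph — conditioning "uniformly given the
edges" is ill-posed for continuous weights — and compare a statistic
against graphs conditioned on size (each edge Bernoulli(1/2)) or on the
observed edge count (uniform via G(n,m); for undirected graphs the dyad
census gives the same null). QAP correlates the upper triangles of two
aligned weighted adjacencies (absent edges contribute 0) and permutes one
network's labels simultaneously in rows and columns. Both use add-one
smoothing, (1+#{draws ≥ obs})/(R+1), so no p-value is ever exactly zero;
default R = 1000. The QAP type-I rate is verified against its nominal
level over independent graph pairs.

## Robustness

The attack module removes nodes one at a time and tracks connectivity
loss: 1 − (surviving connected pairs)/(intact connected pairs). Degree
and betweenness attacks rank once on the intact graph; the cascading
attack recomputes unweighted betweenness after every removal — the
recalculated-betweenness convention, not a load-capacity cascade model.
Ties break by ascending node id, making targeted curves bit-for-bit
reproducible. Random failure averages over 50 sequences by default.

## The synthetic cohort generator

`generate_cohort()` draws from a Gaussian copula: a latent multivariate
normal with block-constant correlation (within_rho inside each block,
between_rho across), transformed per column to lognormal (default),
gamma, or normal marginals by the probability-integral transform. The
copula was chosen over empirical resampling because it has a closed-form
target — the large-n sample Spearman of a latent correlation ρℓ is
(6/π)·asin(ρℓ/2) — which turns generator fidelity into a testable
number. The default spec (`default_cohort_spec()`) is six blocks of 8–12
variables (59 total), within_rho 0.6, between_rho 0.1, 150 subjects:
block counts and cohort size sit in the ranges reported for real
biomarker panels of this kind, and the correlation levels produce
within-block links that survive α = 0.001 at n = 150 while between-block
links mostly do not — i.e. community structure that is present but not
trivial. Outliers are injected post-transform (displacement by a
multiple of the column IQR with random sign), mimicking measurement and
transcription error rather than biological tails; missingness is
MCAR, default 0.

What the generator does *not* emulate: realistic per-biomarker value
ranges and units, longitudinal structure, non-monotone dependence,
block-size heterogeneity beyond what the blocks encode, and informative
missingness.
Passing the planted-recovery tests therefore demonstrates that the
pipeline recovers block-correlated monotone structure at realistic n — it
does not certify performance on real cohorts with confounding or
non-monotone physiology.

## Numerical choices and degenerate inputs

- Pairs with fewer than 4 complete observations, or a constant column on
  the shared subset, are untestable: ρ = NA, p = 1, no edge, no NaN
  propagation.
- |ρ| = 1 maps to p = 0 by convention (the t statistic diverges).
- Power iteration tolerance 1e−10; exhausting 1e5 iterations returns the
  current iterate (in practice convergence is ~tens of iterations).
- Empty-edge graphs: eigencentrality warns and returns zeros; clustering
  returns singletons with undefined Q.
- All stochastic stages draw per-stage seeds from one master seed via
  `derive_seed()` (stage-name hash mod 2³¹), so one integer reproduces a
  full run and stages stay independent.

## Problem sizes used in the checks

The shipped test suite runs the full pipeline at 150 subjects × 59
variables (20 replicate seeds for recovery rates), oracle comparisons at
n ≤ 30 nodes, calibration at 200 null cohorts of 30 variables and 200
QAP pairs at R = 99, and attack ordering on 20 preferential-attachment
graphs of 200 nodes — sizes chosen so each block completes in seconds
while leaving the statistical bands (3 standard errors) meaningful.

## Known limitations

Correlation networks cannot distinguish direct from indirect association,
and no causal reading is intended. The t approximation for Spearman
significance is asymptotic; at very small n (< ~10) exact permutation
p-values would be preferable. Krackhardt efficiency is reported from its
combinatorial definition; published efficiency figures computed by other
toolkits may differ in variant. The map-equation optimizer is two-level
only (no hierarchical coding), and spinglass/overlapping clustering are
out of scope.
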