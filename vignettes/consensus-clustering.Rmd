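---
title: "Estimating the number of clusters by consensus clustering and its fast variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the number of clusters by consensus clustering and its fast variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastconsensus)
```

## The problem

Given an expression matrix $D$ with $n$ items (genes or samples) as rows and
$d$ experimental conditions as columns, how many clusters $k^\*$ does the
data support? Internal validation answers this without external labels by
measuring how *stable* clustering solutions are under perturbation of the
data. The premise: if the data really contain $k^\*$ groups, then clusterings
of random subsamples will keep assigning the same items together at
$k = k^\*$, while at other $k$ the assignments will fluctuate.

## The consensus procedure

For each candidate $k$ in $[k_{\min}, k_{\max}]$ the procedure draws $H$
subsamples $D^{(h)}$, each a uniform random subset of
$\lfloor p \cdot n \rfloor$ rows drawn without replacement, and clusters each
into $k$ groups. Two binary matrices summarise resample $h$: the
connectivity matrix $M^{(h)}(i,j) = 1$ iff items $i, j$ share a cluster, and
the indicator matrix $I^{(h)}(i,j) = 1$ iff both items were drawn into
$D^{(h)}$. The consensus matrix is their normalised ratio

$$\mathcal{M}(k) = \frac{\sum_h M^{(h)}}{\sum_h I^{(h)}},$$

so entry $(i,j)$ is the fraction of subsamples containing both items in
which they co-clustered — a number in $[0,1]$, with 1 meaning "always
together" and 0 "never together". Under perfect, stable clustering the
entries are bimodal at $\{0, 1\}$.

### From matrices to a prediction

Let $m = n(n-1)/2$ and $x_1 \le \dots \le x_m$ be the sorted upper-triangle
entries of $\mathcal{M}(k)$ (the diagonal, fixed at 1 by convention, is
excluded). The empirical CDF is
$\mathrm{CDF}(c) = \sum_{i<j} \mathbf{1}\{\mathcal{M}(i,j) \le c\} / m$, and
the area under the CDF curve is estimated by the right Riemann sum over the
sample points,

$$A(k) = \sum_{i=2}^{m} (x_i - x_{i-1})\,\mathrm{CDF}(x_i).$$

The proportional growth of the area,

$$\Delta(k) = \begin{cases} A(2) & k = 2,\\[2pt]
\dfrac{A(k+1) - A(k)}{A(k)} & k > 2,\end{cases}$$

grows sharply for $k \le k^\*$ and flattens beyond it; the predicted
$k^\*$ is where the $\Delta$ curve stabilises. Because the forward
difference needs $A(k+1)$, the $\Delta$ series ends at $k_{\max} - 1$; no
value exists at $k_{\max}$.

### The plateau rule

Stabilisation is classically judged by eye. For a testable, deterministic
procedure this package fixes a *plateau rule*: the prediction is the
smallest $k \ge 3$ such that $\Delta(j) \le \tau$ for **every** $j$ from $k$
to the end of the series, with $\tau = 0.03$ by default (exposed in the
configuration). An isolated dip below $\tau$ followed by a value above it is
not a plateau. If no plateau exists the prediction falls back to the last
grid point with `stabilized = FALSE`. Notes accompany the prediction: when
$\Delta(2) = A(2)$ — which lives on the absolute area scale, not the
relative-increment scale, so the rule never scans it — is itself below
$\tau$, and when any $\Delta$ is negative ($\Delta \ge 0$ is an empirical
observation, not a theorem; the package monitors it rather than assuming
it). The CDF curves are always attached to the prediction and written to
disk, because visual disambiguation remains the court of last resort.
The `flat_range` field reports the maximal interval on which
$\Delta \le \tau$, surfacing interval-valued ambiguity (benchmark studies
report predictions like "5–6") instead of hiding it.

## FC: the fast variant

The consensus procedure re-draws subsamples for every $k$, so a hierarchical
engine rebuilds $(k_{\max} - k_{\min} + 1) \cdot H$ dendrograms. But nothing
requires fresh subsamples per $k$. FC swaps the two loops: draw $D^{(h)}$
once, build **one** dendrogram on it, and harvest the cuts for every $k$ —
$H$ tree constructions in total. The hierarchically-initialised k-means
engines likewise take all their initial partitions from the one tree.
Crucially this is a *re-ordering*, not an approximation: for a fixed
subsample the cut at $k$ of one tree is identical to re-clustering that
subsample from scratch at $k$. The test suite enforces bit-exact equality
between the fast path and a naive per-$k$ re-clustering reference across
randomized trials; that equality is the central correctness guarantee of
the speed-up. Consensus and FC remain distinct procedures (different
resample streams), and on the synthetic benchmarks their predictions agree
and their $\Delta$ curves are numerically close, which the acceptance tests
check statistically.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `H` | 250 | resampling steps; 250 is robust for datasets with hundreds of items, while 100 suffices for the well-separated synthetic benchmarks used in the tests |
| `p` | 0.80 | subsampling fraction; each resample keeps $\lfloor p\,n\rfloor$ rows |
| `k_min`, `k_max` | 2, 30 | candidate range; `k_max` must not exceed $\lfloor p\,n\rfloor$ (a $k$-cluster solution needs $k$ items), so small datasets force a reduced range |
| `tau` | 0.03 | plateau threshold on $\Delta$ |
| `seed` | — | master seed; each resample uses a deterministically derived child stream |

Sample-size rounding is $\lfloor p\,n\rfloor$ (floor), the conservative
choice. The $\Delta$ increments past $k^\*$ scale roughly with the inverse
of the number of item pairs, so with fewer than ~50 items they hover near
the default $\tau$ and predictions become unstable; the package's own
property tests use $n = 60$ or more for recovery claims.

## Clustering engines

All engines use Euclidean distance. `hier-a`/`hier-c`/`hier-s` are
agglomerative average (UPGMA), complete and single linkage, computed by
`stats::hclust` behind the package's `build_dendrogram()`/`cut_dendrogram()`
surface; cut labels are canonicalised by smallest member index. Ties among
minimal-distance pairs are resolved by `hclust`'s deterministic internal
order — on continuous data ties are a measure-zero event, and determinism,
not any particular tie order, is what the reproducibility contract needs.

`kmeans-r` runs a single Lloyd iteration from a uniform random partition
(redrawn until all $k$ labels occur); `kmeans-a/c/s` start from the
corresponding hierarchical cut of the same subsample. The Lloyd loop is
implemented in the package so that its contract is fully specified: at most
300 sweeps, stop when no label changes, ties in assignment to the
lowest-index centroid, and a deterministic empty-cluster repair (the point
farthest from its current centroid is reassigned to the empty cluster).
One initialisation per call, no restarts — restarts would blur what a
"solution per resample" means in the consensus counts. The test suite
cross-checks the iteration against `stats::kmeans` on repair-free
instances.

## Numerical and degenerate-input choices

* **Never-co-sampled pairs.** With defaults the probability a pair is never
  co-sampled is $(1 - p^2)^H \approx 10^{-102}$ — negligible — but at small
  $H$ it happens; such entries are set to 0 (no evidence of co-clustering)
  and a warning is raised.
* **Diagonal.** Fixed at 1 and excluded from all curve statistics (the CDF
  sums over $i < j$ only).
* **Degenerate area series.** $A(k) = 0$ (a constant consensus matrix) for
  a $k$ used as a denominator raises an error rather than an Inf/NaN
  prediction.
* **$k_{\min}$ and the rule.** The curve machinery requires the grid to
  start at 2 (the $\Delta$ definition anchors there); the plateau rule can
  only return $k^\* \ge 3$, and a prediction of "2" must come from the
  fallback/visual path — the notes flag a small $\Delta(2)$ for exactly
  that purpose.
* **Output precision.** All matrices and curves are written with 12
  significant digits, enough for a re-parse to reproduce the printed values
  exactly.

## The synthetic benchmark generators

The package ships generators emulating three artificial benchmark regimes
with known gold $k$, used by the acceptance tests:

* **gaussian3 analog** — 3 spherical Gaussian classes of 20 items in 200
  dimensions, separation 6 (gold $k = 3$): high-dimensional, well-separated.
* **gaussian5 analog** — 5 classes of sizes 80/120/100/120/80 in 2
  dimensions, separation 6 (gold $k = 5$): low-dimensional, many clusters.
* **simulated6 analog** — 6 classes of sizes 8/12/10/15/5/10 over 600
  features, each with its own disjoint block of 50 marker features shifted
  by +2 noise SDs (gold $k = 6$): marker-block up-patterns.

These are *analogs*: they preserve the gold cluster number and the
qualitative regime, not the original recipes. Two design choices deserve
explanation.

**Separation is measured in units of the total within-class spread.** Each
class is a spherical Gaussian with RMS radius 1 (per-coordinate SD
$1/\sqrt{d}$), and `separation` is the minimum distance between class
means in those units. This makes the difficulty of the recovery problem
independent of dimensionality. Had the per-coordinate SD been fixed at 1
instead, Euclidean distances would concentrate around $\sqrt{2d}$ with a
spread that swamps any moderate mean separation as $d$ grows — at $d = 200$
a separation of 6 is invisible to any distance-based method, which is a
statement about distance concentration, not about cluster structure.

**Class means are placed symmetrically**: a regular simplex when
$d \ge k$ (all pairwise mean distances exactly equal), a regular $k$-gon in
the first two coordinates when $2 \le d < k$, equal spacing on a line when
$d = 1$. Symmetry means that at $k' < k$ the grouping of true classes into
$k'$ super-clusters is decided by sampling noise, so it fluctuates across
subsamples — which is exactly what keeps $A(k')$ below its ceiling for
$k' < k^\*$ and lets the $\Delta$ curve drop at $k^\*$. Asymmetric
placements can make coarse merges stable and shift the apparent $k^\*$
downward; that regime can be explored by passing custom parameters.

**What the generators do not model**: correlated noise, heavy tails, dye
bias, missing values, or down-regulated marker blocks. Passing the recovery
tests shows the procedure identifies exchangeable, spherically-noised
structure; it does not certify performance on real microarray noise.

**A note on the area's monotone growth.** On real, noisy data the area
$A(k)$ is observed to increase with $k$. On *strongly separated* synthetic
data this fails by construction at one point: at $k = k^\*$ the consensus
matrix is exactly binary, so $A(k^\*) = 1$ (only the $0 \to 1$ jump
contributes, at CDF 1), while at $k^\* + 1$ the split-cluster entries
spread into $(0,1)$ and the Riemann sum drops. The resulting negative
$\Delta(k^\*)$ is harmless for the plateau rule (negative values satisfy
$\Delta \le \tau$) and is reported in the prediction notes. The monotone
growth property is therefore asserted on the structureless null generator,
where it holds throughout.

## Problem sizes used by the test suite

The recovery tests run FC with $H = 100$ on the three analogs ($n = 60$,
500 and 60), $k \in [2, 10]$, 10 seeds each. The consensus-versus-FC
agreement tests use $H = 250$ — the setting at which the stability
estimates are converged for datasets with hundreds of items — raised to
$H = 500$ for the smallest analog, whose $\Delta$ estimates are noisiest
(the variance of $A(k)$ scales inversely with both the resample count and
the number of item pairs). The fast-path exactness trials use $n \le 30$,
$H \le 20$; oracle comparisons against brute-force agglomeration use
$n \le 12$. These sizes exercise every claim at full fidelity while
keeping a complete test run in the minutes range on one core.

## Worked example

```{r example}
set.seed(7)
d <- gaussian_clusters(c(20, 20, 20), n_dims = 200, separation = 6)
fit <- estimate_k(d$data, method = "fc", algorithm = "hier-a",
                  H = 100, p = 0.8, k_max = 10, seed = 7)
fit$prediction
round(fit$curves$area, 3)
round(fit$curves$delta, 3)
```

The area saturates at $k = 3$ and the $\Delta$ curve stays below
$\tau = 0.03$ from there on: the plateau rule returns $k^\* = 3$, the
gold answer. The same fit exposes the consensus matrices
(`fit$result$matrices`), reusable as dissimilarities via
`consensus_to_dissimilarity()`.

## Known limitations

* The plateau rule is a fixed operationalisation of a visual judgement; on
  data where the $\Delta$ curve hovers around $\tau$ (small $n$, weak
  structure) predictions flip between adjacent $k$. Inspect the attached
  CDF curves and `flat_range` before trusting a marginal call.
* Memory holds one pair of $n \times n$ integer accumulators per active
  $k$ (FC holds the whole range concurrently); practical up to a few
  thousand items.
* Runs are single-threaded by contract — results are defined by one
  deterministic stream per resample; parallelism could be added without
  changing results but is not provided.
* NMF-based engines are deliberately out of scope.
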