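---
title: "Network propagation enrichment with the Xd statistic: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network propagation enrichment with the Xd statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xdnet)
```

## The model

`xdnet` ranks associations between a target gene/protein set and a
collection of reference sets using the structure of a weighted molecular
interaction network rather than only shared membership. The statistic has
three layers.

**Propagation.** A random walk with restart from the mapped target nodes,
`p ← (1 − r) T p + r p0`, where `T` column-normalizes edge weights
(weights act as relative transition propensities — the standard convention;
an unweighted network is simply the all-weights-1 special case) and `p0` is
uniform over the seeds. The restart probability `r` trades local against
global network information; the default `r = 0.9` emphasizes the seeds'
immediate neighbourhood. Despite its name, the procedure is fully
deterministic. The walk accounts for both the number and the length of paths
connecting two nodes, which is what a shortest-path distance cannot do.

**Distances and bins.** Steady-state relevance is converted to distances by
`d = 1 − p`, the distances of every reference set's mapped members are
pooled into a background, and the pooled distribution is cut into `n = 10`
bins. We read "equal-sized bins" as *equal-frequency* (quantile) bins on the
pooled distances: RWR relevance spans orders of magnitude, so equal-width
bins over [0, 1] would put nearly all mass into the top bin and the
statistic would be driven by ties. Quantile binning makes the background
near-uniform (`P_ia ≈ 1/n`) and profile deviations directly interpretable.
Equal-width binning remains available (`binning = "width"`) for sensitivity
analysis, as does a fallback to it when the pooled values carry fewer
distinct values than bins.

**The Xd score.** For reference set `c`,
`Xd = Σ_{i=1..n} (P_ic − P_ia)/i` with all `P` as fractions in [0, 1]. The
`1/i` weight encodes the assumption that an over-representation of *short*
distances is stronger evidence of association than one of long distances,
and shields the score from high-degree/long-distance outliers. Fractions
(not percentages) and no `1/n` factor are the default because they
reproduce the score magnitudes the method is known for (scores of roughly
0.2–0.8 for strong associations, thresholds near 0.4–0.7 on real
interactomes); a `normalize = TRUE` flag divides by `n` for users who want
the alternative reading, since the original formula's normalization is not
recoverable unambiguously.

Target genes that are also members of a reference set contribute their small
self-distances to that set's profile: overlap is deliberately rewarded,
which is what produces the strong correlation between Xd and
overlap-significance exploited below.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `restart_prob` | 0.9 | restart probability; higher = more local. The iteration contracts with factor `1 − r`, so convergence at 0.9 takes ~a dozen iterations. |
| `n_bins` | 10 | distance bins; enough sensitivity without starving bins. |
| `tol`, `max_iter` | 1e-10, 1000 | L1 convergence control; tight tolerance is essentially free at `r = 0.9`. |
| `q_cut` | 0.05 | adjusted-p level the Xd threshold is calibrated to. |
| `min_mapped` | 10 | advisory minimum mapped target size — warns, never blocks, so small examples run. |
| `universe_mode` | network nodes | contingency-table universe; the network universe puts ORA and Xd in the same gene space, a precondition for the calibration regression. |

## The over-representation baseline and calibration

The baseline is the one-sided Fisher's exact test (exact log-space tail
summation, no approximation) with Benjamini–Hochberg adjustment. Because Xd
and overlap significance correlate strongly for overlapping pairs, an OLS
fit of `xd` on `−log10(q)` converts a familiar q-value cutoff into an Xd
cutoff: the threshold is the *upper bound of the 95% confidence band for the
mean response* at `−log10(0.05)`, so fit uncertainty raises the bar. Design
choices made where the procedure was genuinely open:

* the regression is on `−log10(q)`, not raw `q` — raw q against Xd is
  grossly nonlinear while the log scale is consistent with the high Pearson
  correlations the approach relies on; `transform = "raw"` exists for
  comparison;
* the band is the confidence band for the mean response, not the prediction
  band (`band = "prediction"` available) — the threshold targets the
  *expected* Xd of a set at the q cutoff, not a new set's sampling spread;
* zero-overlap pairs are excluded from the fit (their q is 1 by
  construction and carries no overlap information) but are still ranked and
  thresholded — they are precisely the novel-association candidates;
* with fewer than 3 usable points the calibration is declared unavailable
  and a fallback threshold of 0.5 is used with a warning (the midpoint of
  the threshold range seen on real interactome-scale collections).

## Tissue-restricted scores

For each tissue label, member distances are filtered to nodes annotated for
the tissue *and the background is re-pooled under the same filter*. A
matched background avoids scale artifacts between tissues with different
annotation coverage. A tissue in which a set retains no annotated member
yields `NA` ("not scorable in this tissue"), never 0 — 0 is a meaningful
score (no deviation from background). A Mann–Whitney convenience wrapper
(`compare_tissue_groups()`) tests whether a tissue group's scores are
shifted upward.

## Benchmark statistics

For method comparison, a consensus benchmark is the intersection of the
top-100 prefixes of externally produced rankings, and a ranking is scored by
the normalized KS running sum: `+sqrt((m−h)/h)` per benchmark member,
`−sqrt(h/(m−h))` otherwise, enrichment score = maximum prefix sum (one-sided
by default — enrichment at the top is the question being asked; a two-sided
max-|deviation| variant sits behind a flag). Permutation p-values use the
add-one estimator `(1 + #{es* ≥ es}) / (n_perm + 1)`, floored at 0.001 for
the default 1000 permutations. Because the score depends only on the
benchmark members' positions, permutations draw the `h` positions uniformly
among `m` ranks instead of shuffling the whole list — identical in
distribution, much cheaper.

## The synthetic world

The generator emulates, at desk scale, the situation the method is built
for:

* **Topology.** 300-node preferential-attachment network (`m = 2` edges per
  node) — interactomes are heavy-tailed; a configuration-model alternative
  is behind a flag. Base edge weights U[0.15, 1] echo a STRING-like
  confidence spread.
* **Sets.** Eight disjoint 30-gene pathways; a 15-gene target.
* **Graded overlap.** The target is drawn from four non-planted pathways
  with counts 6/4/3/2. This is the one genuinely open design dimension and
  the choice is deliberate: a real collection offers the calibration a
  spectrum of overlap q-values spanning decades; with only eight sets the
  generator must provide that spectrum itself, otherwise every q sits near 1
  and the regression extrapolates into absurd thresholds. The graded design
  also pins the planted pathway at exactly **zero** overlap, making it a
  pure network-association — the scenario the method claims to detect and
  ORA cannot.
* **Planting.** Each target × planted-pathway pair gains an edge with
  probability `p_conn` (default 0.3), weight U[0.5, 1] (high-confidence
  range).
* **Tissues.** One label covers the planted pathway's nodes plus ~30% of
  the rest; a second label covers an independent ~50% of nodes.

What a green planted-recovery test establishes: the pipeline detects a
dense, high-confidence wiring pattern between a target and a zero-overlap
pathway against seven matched controls, and the calibrated threshold admits
it. What it does **not** establish: performance on real interactomes (degree
distribution, edge-confidence structure and pathway overlap patterns are all
simplified), robustness to identifier noise, or any biological claim.

## Numerical choices and degenerate inputs

* Duplicate edges collapse by **max** weight (conservative toward
  connectivity); self-loops are dropped with a warning, not an error.
* Isolated/dangling nodes: their walk mass is redirected to the restart
  distribution each iteration, so probability is conserved to 1e-9
  regardless of topology.
* Bins are left-closed/right-open with the last bin closed; values outside
  the edge range clamp into the boundary bins.
* Quantile ties or too few distinct pooled values trigger the equal-width
  fallback with a warning; all-identical distances degenerate to one
  occupied bin rather than erroring.
* Component-size ties in `largest_component()` resolve toward the component
  containing the lexicographically smallest node id; all outputs are sorted,
  so repeated runs are byte-identical.
* Seeds absent from the network are dropped with a count; an entirely
  unmapped seed set is an error.
* BH q-values are clamped to `q ≥ p` to keep the step-up inequality exact
  under floating-point rounding.

## Known limitations

* Identifier matching is exact and case-sensitive; no cross-namespace
  mapping is attempted — harmonize upstream.
* The calibration needs overlapping pairs; on collections where the target
  overlaps nothing, the fallback threshold applies and should be treated as
  a rough default, not a calibrated value.
* Tissue scores share one global walk; a tissue-specific *network* (edges
  present only in a tissue) is out of scope.
* The benchmark module consumes externally produced rankings; it does not
  re-implement expression-based enrichment methods to generate them.
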