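# xdnet — network-based gene set enrichment with the Xd statistic

Classical over-representation analysis (ORA) scores the association between
an experimentally derived gene list and a known pathway purely by counting
shared genes. That misses associations carried by the *wiring* of a molecular
interaction network: a disease gene set can be densely interconnected with a
pathway it barely overlaps. `xdnet` scores such associations by network
propagation, for users (geneticists, systems biologists) who have a plain
gene/protein list — no expression measurements — and want pathway
associations ranked with network evidence, with tissue-restricted scores and
exportable sub-network views of each association.

## Method

Given a weighted undirected interactome `G` (confidence weights in (0, 1]),
a target set `S` and reference sets `C_1..C_K`:

1. **Random walk with restart (RWR).** Iterate
   `p ← (1 − r) T p + r p0` with `T` the column-stochastic transition
   operator (weight-proportional), `p0` uniform over the mapped target
   nodes, and restart probability `r = 0.9` (local-neighbourhood emphasis).
   The fixed point gives each node's steady-state relevance; distances are
   `d(v) = 1 − p(v)`.
2. **Xd statistic.** Pool the distances of all reference-set members into a
   background, discretize into `n = 10` equal-frequency bins, and score each
   reference set by

   `Xd(c) = Σ_{i=1..n} (P_ic − P_ia) / i`

   where `P_ic` is the fraction of set `c`'s member distances in bin `i` and
   `P_ia` the background fraction. The `1/i` weight rewards an excess of
   *short* distances and damps long-distance/high-degree outliers.
3. **ORA baseline.** One-sided Fisher's exact test on the overlap over the
   network-node universe, Benjamini–Hochberg adjusted.
4. **Calibrated threshold.** Xd and overlap significance are strongly
   correlated for overlapping pairs; `xd ~ −log10(q)` is fitted by OLS and
   the Xd significance cutoff is the upper 95% confidence bound of the mean
   response at `q = 0.05`.
5. **Extras.** Tissue-restricted Xd (distances and background filtered to a
   tissue's nodes), benchmark evaluation via the normalized
   Kolmogorov–Smirnov running-sum enrichment score with permutation
   p-values, annotated sub-network extraction (GraphML/TSV), and a seeded
   synthetic-data generator with planted target↔pathway associations.

## Worked example

The package ships a small synthetic fixture (300-node scale-free network,
8 pathways of 30 genes, a 15-gene target drawn from four of them with graded
overlap, and pathway `P1` *planted*: wired to the target with extra
high-confidence edges but sharing **zero** genes with it):

```r
library(xdnet)
dir <- system.file("extdata", "fixture", package = "xdnet")
net     <- read_edge_list(file.path(dir, "network.tsv"))
target  <- read_gene_list(file.path(dir, "target.txt"))
paths   <- read_gmt(file.path(dir, "pathways.gmt"))
tissues <- read_tissue_annotations(file.path(dir, "tissues.tsv"))
res <- run_xd_analysis(net, target, paths, tissue = tissues)
print(res)
```

```
<xd_result> 8 reference sets, threshold 0.08725, 1 flagged significant
  set_id    xd_score n_mapped overlap    fisher_p   fisher_q significant_flag
1     P1  0.35710317       30       0 1.000000000 1.00000000             TRUE
2     P2  0.04718254       30       6 0.001601071 0.01280857            FALSE
3     P3  0.01535714       30       4 0.050872145 0.20348858            FALSE
4     P4 -0.03732804       30       3 0.180008031 0.48002142            FALSE
...
```

Read this as: the planted pathway `P1` shares no genes with the target
(`overlap = 0`, Fisher q = 1 — invisible to ORA) yet tops the Xd ranking at
0.357, well above the calibrated significance threshold 0.087, because the
walk reaches its members through many short, high-confidence paths. The
overlap-anchored pathways `P2`–`P5` line up with their q-values
(calibration fit: `xd = -0.052 + 0.057 · (−log10 q)`, Pearson r = 0.93),
which is exactly the correlation the threshold calibration exploits.
Per-tissue columns (`xd_brain`, `xd_generic`) re-score each pathway using
only nodes annotated to that tissue.

Sub-network view of the P1 association (the interpretable artifact):

```r
mt <- map_set(target, net, min_mapped = 10)
mr <- map_set(paths$P1, net, min_mapped = 1, role = "reference")
sub <- largest_component(extract_subnetwork(net, mt, mr, include_bridges = TRUE))
write_subnetwork(sub, "subnet_P1.graphml")
```

## Command line

```sh
Rscript inst/scripts/xdnet score --network net.tsv --target genes.txt \
    --gmt pathways.gmt --tissue tissues.tsv --out results/
Rscript inst/scripts/xdnet benchmark --ranking ranking.tsv --benchmark bench.txt
Rscript inst/scripts/xdnet simulate --seed 7 --out fixture/
Rscript inst/scripts/xdnet subnet --network net.tsv --target genes.txt \
    --gmt pathways.gmt --set-id P1 --bridges --lcc
```

All options can be seeded from a flat `key: value` config file
(`--config run.yaml`); explicit flags win.

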