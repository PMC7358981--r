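# dmnph — persistent homology of resting-state brain functional networks

`dmnph` analyses weighted functional connectivity networks of the default
mode network (DMN) with zeroth-dimensional persistent homology, for studies
that compare two groups of subjects (for example carriers versus
non-carriers of a genetic risk allele) on resting-state fMRI.

Conventional graph-theoretic comparisons of functional networks depend on
an arbitrary edge threshold. The persistent-homology approach removes that
choice: thresholding the network at every value at once yields a *graph
filtration*, whose topology (for connected components) changes exactly at
the weights of the minimum spanning tree (MST). The package implements:

* **Connectivity**: edge weights `W_ij = 1 − Pearson r` between
  ROI-averaged BOLD series — a dissimilarity in `[0, 2]` — over a packaged
  26-node AAL90 DMN atlas (13 regions per hemisphere), with whole-brain,
  left- and right-hemisphere scopes.
* **Filtration**: Kruskal MST, filtration values `λ₀ = 0 ≤ λ₁ ≤ … ≤
  λ_{m−1}` (the MST weights), the Betti-number curve `β₀(λ)` (connected
  components, from `m` down to 1), and the single-linkage merge dendrogram.
* **Persistent features**: the integrated persistent feature curve
  `IPF_{λᵢ} = (m−i)/(m(m−1)) · Σ_{k>i} λ_k`, and the per-subject scalars
  **SIP** (OLS slope of IPF against λ) and **BNP** (OLS slope of β₀
  against λ) — both more negative when network components aggregate faster.
* **Comparison graph measures**: characteristic path length, global
  efficiency, network radius (on `W` as edge lengths), modularity (Louvain,
  best of 10 restarts) and eigenvector centrality (power iteration) on the
  affinity `max(0, 1 − W)`.
* **Group inference**: two-sided permutation tests (default 10,000 label
  shuffles, add-one correction) for every feature × scope cell.
* **Synthetic cohorts**: a generator with hemisphere-block correlation
  structure, homotopic bridges, subject-level variability, and a planted
  "faster aggregation" group effect, so the whole pipeline is testable
  without access-controlled imaging data.

## Worked example

```r
library(dmnph)

cfg <- cohort_config(n_carrier = 8, n_noncarrier = 8, seed = 42)
coh <- simulate_cohort(cfg)
coh
#> Synthetic cohort: 8 carrier + 8 noncarrier subjects, 26 ROI x 130 timepoints

W <- build_network(coh$subjects[[1]]$values, "both")
prof <- betti0_curve(W)
head(cbind(prof$lambda, prof$betti0), 5)
#> lambda 0.000 0.280 0.311 0.311 0.315 ...
#> betti0    26    25    24    23    22 ...

round(subject_features(W, seed = 1), 4)
#>      sip      bnp      cpl       nr       ec      mod       gc
#>  -1.1327 -60.3282   0.6497   0.7916   0.1957   0.1185   1.6186

compare_groups(coh, n_perm = 1000, seed = 7)
#> Two-group permutation comparison (carrier vs noncarrier, 1000 permutations, statistic = mean)
#>          SIP    BNP    CPL     NR     EC    MOD     GC
#> both  0.0140 0.9031 0.3357 0.5854 0.0999 0.1728 0.3646
#> left  0.4705 0.3227 0.1808 0.1868 0.0549 0.0300 0.2488
#> right 0.4735 0.2028 0.2008 0.2438 0.2328 0.3467 0.2318
```

Reading the output: the filtration of this subject's whole-brain network
starts with 26 separate components at `λ = 0` and merges them as λ grows;
`sip = -1.13` and `bnp = -60.3` are the aggregation-rate slopes (more
negative = faster aggregation), and the remaining columns are the five
graph measures. The grid printed by `compare_groups()` holds the
permutation p-values per scope and feature; at these small group sizes
only occasional cells fall below 0.05. With the default cohort sizes
(27 + 31) the planted homotopic-coupling boost is detected by SIP and BNP
in a majority of simulated cohorts, with smaller mean p-values than the
path-based measures — see the acceptance tests and the vignette
(`vignettes/persistent-homology-dmn.Rmd`) for the full validation design
and the reasoning behind the generator.

Real data enter through `read_cohort("manifest.tsv")` (a TSV mapping
`subject_id`, `group`, `path` to per-subject ROI × time series files in
atlas row order; trim leading volumes with `n_discard` in
`feature_table()`), or as precomputed connectivity matrices attached as
`network` elements of the cohort subjects.

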