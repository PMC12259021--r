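# stagehet

Stage-wise transcriptional heterogeneity and gene-program scoring for
single-cell RNA-seq.

Multi-stage single-cell studies of premalignant progression — e.g. the lung
adenocarcinoma sequence normal → AAH (atypical adenomatous hyperplasia) →
adenoma → AIS (adenocarcinoma in situ) — repeatedly ask whether cells become
transcriptionally more heterogeneous as lesions advance, and whether
particular gene programs switch on in particular subpopulations along the
way. `stagehet` is an R package for analysts working on such designs. It
provides:

* **the within-stage heterogeneity statistic**: median pairwise normalized
  mutual information between discretized cell profiles under repeated
  subsampling, with stage comparisons;
* the surrounding pipeline: cell/gene QC, library-size log normalization,
  one-vs-rest Wilcoxon marker ranking, feature-panel construction,
  expression-bin-matched gene-set module scores, gene-set and cell-group
  Pearson correlations, 10x-style Matrix Market I/O;
* a negative binomial multi-stage count **simulator with known ground
  truth** (cell types, a per-stage heterogeneity knob, injectable gene
  programs), so every step is testable without external data.

## The statistic

Each cell is reduced to a profile of bin indices over a feature panel
(per-gene equal-width binning into *B* = 10 bins). For cells *x*, *y*, with
p(x), p(y) the empirical bin-frequency distributions over panel genes and
p(x, y) the joint distribution of gene-aligned bin pairs:

    I(x, y)   = Σₓ Σᵧ p(x, y) log [ p(x, y) / (p(x) p(y)) ]        (nats)
    NMI(x, y) = I(x, y) / sqrt( H(x) H(y) )                        ∈ [0, 1]

Within each stage, `n_cells` cells (default 100) are subsampled `n_draws`
times (default 500); the median of all pairwise NMIs per draw gives the
stage's distribution of draw medians, which equalizes stages of different
sizes. High medians = homogeneous stage; falling medians = growing
cell-to-cell heterogeneity. Stage pairs are compared with a two-tailed
unpaired Student's t-test (exact-enumeration Mann–Whitney available); the
output flags that draw medians are resampled, not independent.

## Worked example

```r
library(stagehet)

# four simulated stages with increasing cell-private transcriptional jitter
sim  <- simulate_counts(sim_config(n_genes = 1000, cells_per_stage = 300, seed = 1))
qc   <- filter_cells(sim, qc_thresholds(umi_min = 500, genes_min = 100))
print(qc$report)
#> <qc_report> 1200 cells in, 1131 retained (69 excluded)
#>   failed UMI bounds: 26 | gene bounds: 3 | mito fraction: 41

norm    <- normalize_counts(filter_genes(qc$data, qc_thresholds(gene_min_cells = 10)))
markers <- rank_markers(norm, top_m = 50)                 # one-vs-rest Wilcoxon
panel   <- build_panel(markers, pca_loadings(norm, 10), 50, 50, 10)
disc    <- discretize(norm, panel, n_bins = 10)
het     <- stage_heterogeneity(disc, norm$cells, n_cells = 100,
                               n_draws = 100, seed = 1)
print(het)
#> <stage_nmi> 4 stages, 100 draws of 100 cells, 10 bins
#>   normal       median NMI 0.1267  (IQR 0.1257-0.1275, n_cells = 100)
#>   AAH          median NMI 0.1116  (IQR 0.1108-0.1124, n_cells = 100)
#>   adenoma      median NMI 0.1019  (IQR 0.1014-0.1024, n_cells = 100)
#>   AIS          median NMI 0.0992  (IQR 0.0986-0.0998, n_cells = 100)
```

The median draw-median NMI falls strictly along the progression — the
simulated stages were generated with increasing per-cell jitter, and the
statistic recovers that ordering. `compare_stages(het)` separates every
adjacent pair decisively (e.g. normal vs AAH at p ≈ 1e-161 on 100 draw
medians; treat such p-values as descriptive, as the caveat column notes).
`plot(het)` draws the stage-wise boxplots.

Module scores against bin-matched background genes:

```r
ms <- module_score(norm, my_gene_set, n_expr_bins = 24, n_ctrl_per_bin = 100,
                   seed = 1)
geneset_correlation(ms, other_ms)    # Pearson r, Fisher-z 95% CI, t-test p
group_correlation(norm, "stage")     # group-mean Pearson matrix, top 1000 variable genes
```

A full run (QC → panel → NMI → comparisons → scores → correlations, with
TSV/JSON outputs and a run manifest) is `run_pipeline(pipeline_config(...))`
or, from a shell, the thin wrapper:

```sh
Rscript exec/stagehet simulate --out fixture --seed 1
Rscript exec/stagehet het --in fixture --out results --n-draws 500 --seed 1
```

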