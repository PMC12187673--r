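# clustgauge

Quantify how clustering parameters drive single-cell RNA-seq clustering
accuracy — and predict that accuracy without labels, from intrinsic
cluster-validity indices.

## The problem

Leiden community detection on a kNN graph is the standard way to cluster
cells, but its result depends on five upstream choices: the number of
principal components (PC), the neighborhood size (NN), the
neighbor-weighting method (Gaussian kernel vs. UMAP fuzzy simplicial
set), the distance metric (cosine vs. Euclidean), and the community
resolution (Res).  With curated labels one can measure the accuracy of
every configuration directly; without labels one needs a proxy.
`clustgauge` provides both instruments:

* **Parameter → accuracy.**  A full-factorial sweep over
  PC × NN × Res × method × metric (the default grid has
  4 × 3 × 4 × 2 × 2 = 192 configurations) on stratified 20% subsamples
  of a labeled dataset, scored by majority-vote accuracy, the adjusted
  Rand index ARI = (Σᵢⱼ C(nᵢⱼ,2) − E)/(max − E), and NMI =
  MI(p,q) / mean(H(p), H(q)).  The accuracy surface is modeled by robust
  Huber regression (IRLS, c = 1.345, MAD scale) on treatment-coded
  factors with all first-order interactions and a sum-to-zero subsample
  block — reference levels Gauss / Res 0.5 / PC 10 / NN 10 / cosine.
* **Indices → accuracy.**  Fifteen intrinsic validity indices per
  clustering (TSS, within-cluster dispersion Σₖ Σ_{i∈Cₖ}‖xᵢ−cₖ‖²,
  Ball–Hall, Banfield–Raftery Σₖ nₖ ln(Tₖ/nₖ), PBM, Wemmert–Gancarski,
  Xie–Beni, Ray–Turi, McClain–Rao, C-index, Dunn, Silhouette,
  Point-Biserial, SD-scattering, SD-separation), fed to an elastic net
  `(1/2n)Σ(y−ŷ)² + α(ρ‖β‖₁ + ((1−ρ)/2)‖β‖₂²)` with ρ = 0.5 and α chosen
  by 5-fold CV, validated leave-one-replicate-out within a dataset and
  across datasets, with sign-consistent feature ranking.

A negative-binomial synthetic-data generator with known population
labels (unequal cluster sizes, marker-gene blocks, library-size
variation) exercises the whole pipeline end to end; real 10x-style
Matrix Market data with a label TSV can be loaded with
`read_dataset_10x()`.

## Worked example

```r
library(clustgauge)

spec <- population_spec(
  n_cells_per_cluster = c(150, 120, 100, 80, 60, 50, 40, 30),
  n_genes = 1200, n_marker_genes_per_cluster = 25,
  log_fold_change = 1.2, dispersion = 1.5, seed = 42
)
ds <- generate_dataset(spec)
ds
#> synthetic_dataset: 630 cells x 1200 genes, 8 populations
#> pop01 pop02 pop03 pop04 pop05 pop06 pop07 pop08
#>   150   120   100    80    60    50    40    30

subs <- stratified_subsample(ds$labels, fraction = 0.2, n_replicates = 5, seed = 42)
cfg <- sweep_config(pcs = 10L, neighbors = c(10L, 30L),
                    resolutions = c(0.5, 0.8, 1, 2),
                    methods = "umap", metrics = "cosine", seed = 42)
records <- run_sweep(ds, subs, cfg, dataset_id = "demo", n_hvg = 500L)
aggregate(cbind(accuracy, n_clusters, wc_dispersion) ~ res, records, mean)
#>   res  accuracy n_clusters wc_dispersion
#> 1 0.5 0.2998236   2.888889      16748.26
#> 2 0.8 0.3817460   6.500000      13794.24
#> 3 1.0 0.4039683   7.900000      12892.41
#> 4 2.0 0.4730159  14.700000      10053.37

fit <- fit_robust_effects(build_design(records, default_design_spec(records)))
fit
#> Huber-IRLS effect fit: 12 coefficients, r2 = 0.9027, rmse = 0.02433,
#> bias = -0.00152 (converged in 36 iters)
round(fit$coefficients[c("(Intercept)", "res:2", "nn:30")], 4)
#> (Intercept)       res:2       nn:30
#>      0.3238      0.1524     -0.0526
```

Reading the output: at resolution 0.5 Leiden recovers only ~3 of the 8
true populations, and accuracy sits near 0.30; at resolution 2 it
recovers ~15 communities and accuracy climbs to 0.47.  The robust fit
quantifies this — moving Res from 0.5 to 2 adds 0.15 accuracy at the
reference levels, while raising NN from 10 to 30 costs 0.05.  The
within-cluster dispersion column falls as accuracy rises
(Spearman ρ = −0.93 here), which is exactly why it works as a label-free
accuracy proxy:

```r
sel <- is.finite(records$wc_dispersion)
cor(records$wc_dispersion[sel], records$accuracy[sel], method = "spearman")
#> [1] -0.9330331
```

The one-call version — three synthetic datasets, subsampling, sweep,
effect model, metric correlations, elastic-net validation, all output
files — is:

```r
res <- run_pipeline(default_run_config(1L), out_dir = "out")
```

A thin CLI over the same functions lives in `inst/cli/clustgauge.R`
(subcommands `simulate`, `sweep`, `metrics`, `effects`, `predict`,
`run-all`).

## Package layout

* `R/synthetic-data.R` — population specs, NB generator, stratified
  subsampling
* `R/preprocess.R`, `R/neighbors.R` — filtering, normalization, HVG,
  PCA, Gauss/UMAP kNN graphs
* `R/cluster-sweep.R` — factorial grid, Leiden clustering, sweep runner
* `R/scoring.R` — majority-vote accuracy, ARI, NMI
* `R/intrinsic-metrics.R` — the fifteen validity indices
* `R/effect-model.R` — design coding, Huber IRLS, Kruskal–Wallis/Dunn,
  extreme configurations
* `R/predictor.R` — elastic net, intra/cross validation, feature
  ranking, metric association, linearity deviation
* `R/pipeline.R` — one-call orchestration and output files

See the vignette (`vignettes/clustering-parameter-sweeps.Rmd`) for the
model details, parameter rationale and known limitations.
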