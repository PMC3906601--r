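# inteqtl

Integrative multi-omics sparse regression for gene-expression traits.

## The problem

Tumor studies routinely measure several genomic layers on the same
samples — copy-number alterations (GISTIC cytoband calls in
{-2,-1,0,1,2}), DNA methylation (beta-values in [0,1]) and miRNA
expression — alongside gene expression. Asking, layer by layer, which
features correlate with each gene invites trouble: features are
correlated *across* layers, so separate per-layer analyses accumulate
redundant, indirect associations, and the relative contribution of each
layer to expression variation cannot be read off.

`inteqtl` treats each gene's expression as a quantitative trait and
explains it by **all layers jointly**. For gene *k* with centred trait
vector **y**_k and feature blocks **X**^(m) (samples × J_m, z-scored),
it solves the lasso on the concatenated design,

    min_beta  sum_i ( y_ik - sum_m beta^(m) . x_i^(m) )^2
              + lambda * sum_m || beta^(m) ||_1 ,

with lambda chosen by 10-fold cross-validation, wrapped in a two-stage
Screen-and-Clean procedure: lasso screening on one half of the samples,
OLS t-tests on the other half, keeping features with p <= 0.05. The
magnitude of a cleaned coefficient is the **association strength**; the
strengths feed every downstream analysis — thresholded edge sets
(rho = 0.1 for analytics, 0.3 for networks), a Venn classification of
genes by associated layer, decile-wise prediction accuracy, top-K
relative contribution per layer, hub features, and a bipartite
feature-gene association network with modularity and square-clustering
diagnostics. Single-layer baseline fits use the identical machinery for
comparison.

A synthetic multi-omics generator with known sparse ground truth (and
cross-type feature correlation, the mechanism behind spurious
single-layer associations) supports benchmarking; the package's central
claims — the integrative fit predicts expression better and produces
fewer spurious associations than any single-layer analysis — are
verified on it in the test suite.

It is aimed at computational biologists who have feature-level matrices
in hand (this package does not download or preprocess raw array data)
and want a principled joint analysis with reproducible, text-file
outputs.

## Worked example

```r
library(inteqtl)

cfg <- sim_config(N = 150, J = c(CNA = 6, methylation = 60, miRNA = 20),
                  genes = 30, seed = 42)
sim <- simulate_multiomics(cfg)
dataset <- normalize_dataset(sim$dataset)

fit <- ieqtl(dataset, mode = "integrative",
             control = ieqtl_control(seed = 1))
fit
#> <ieqtl> mode=integrative  30 genes fitted (N=150 samples)
#>   selected features per gene: median 3 (range 0-6)

edges <- extract_edges(fit, rho = 0.1)
nrow(edges)
#> [1] 94
classify_genes(edges)$counts
#>                   CNA           methylation                 miRNA
#>                     6                     6                     0
#>       CNA+methylation             CNA+miRNA     methylation+miRNA
#>                     3                     1                     7
#> CNA+methylation+miRNA
#>                     4

hub_features(edges, top_n = 3)
#>   feature_id feature_type degree
#> 1    cna_002          CNA      6
#> 2    cna_004          CNA      6
#> 3    cna_005          CNA      6

recovery_metrics(fit, sim$truth, rho = 0.1)$overall
#> precision   recall      f1  rmse_support   tp   fp   fn
#>     0.809    0.938   0.869         0.212   76   18    5

net <- build_network(edges, rho = 0.3)
topology_summary(net)$modularity
#> [1] 0.726
```

Reading the output: 30 simulated genes were fitted jointly on 86
features across three layers; 94 associations survive the confidence
threshold rho = 0.1. The Venn counts partition the genes with at least
one association by which layers they associate with (the `+` classes
are the "synergistic" genes). The three top hubs are CNA cytobands
touching 6 genes each — copy-number features are few but broad, so they
accumulate degree. Against the generator's ground truth, 93.8% of true
(gene, feature) pairs are recovered at 80.9% precision; the RMSE here
is dominated by a handful of missed large effects. The rho = 0.3
network splits into 4 components with modularity Q = 0.73.

Real data enter through `read_feature_matrix()` /
`read_expression_matrix()` (features × samples TSV),
`read_gistic_lesions()` for GISTIC lesion tables, then
`variance_filter()` → `align_samples()` → `normalize_dataset()`.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/inteqtl.R simulate --seed 1 --out data/
Rscript inst/cli/inteqtl.R all --data data/ --seed 1 --out run/
```

with subcommands `simulate`, `fit`, `analyze`, `network`, `benchmark`,
`all`; identical seeds give byte-identical outputs.

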