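---
title: "Integrative multi-omics sparse regression: model, procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative multi-omics sparse regression: model, procedure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`inteqtl` treats each gene-expression trait as a quantitative phenotype
explained jointly by heterogeneous genomic features. For gene $k$ with
centred trait vector $y_k \in \mathbb{R}^N$ and $M$ feature blocks
$X^{(m)} \in \mathbb{R}^{N \times J_m}$ (copy-number cytoband calls,
methylation beta-values, miRNA expression), the integrative model is the
additive linear model

$$ y_{ik} = \sum_{m=1}^{M} \beta^{(m)} \cdot x^{(m)}_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2), $$

fitted by L1-penalised least squares on the concatenated design:

$$ \min_\beta \; \sum_i \Big(y_i - \textstyle\sum_m \beta^{(m)} \cdot
x^{(m)}_i\Big)^2 \; + \; \lambda \sum_m \lVert \beta^{(m)} \rVert_1 . $$

A single penalty $\lambda$ applies to the concatenated coefficient vector,
so the integrative problem *is* a plain lasso on the stacked design — the
blocks compete for explanatory power on an equal footing, which is what
suppresses the indirect associations that separate per-type analyses
accumulate. There is no intercept: traits are centred per gene, and every
feature column is z-scored (see below). The single-type baseline applies
the identical machinery to one block at a time.

Because the features are standardized, a coefficient magnitude is directly
interpretable as an association strength, and all downstream thresholds
($\rho$) act on that scale.

## Why features are z-scored with the population convention

Feature columns are normalized to mean 0 and standard deviation 1 computed
with denominator $N$ (not $N-1$), so that $x_j^\top x_j = N$ exactly for
every standardized column. This makes the coordinate-descent stationarity
condition and the subgradient bound $\lambda_{\max} = 2\max_j |x_j^\top y|$
exact identities rather than approximations. CNA calls, although
categorical in $\{-2,\dots,2\}$, enter the same linear model and are
z-scored like every other feature.

Expression traits are centred per gene but **not** variance-scaled:
coefficient magnitudes therefore remain comparable across feature types
while still reflecting the trait's scale. Variance-scaling the traits
would have made strengths unit-free, but it would also silently reweight
genes relative to one another in every strength-thresholded analysis; we
prefer the interpretation "change in expression (in trait units) per SD of
feature". This choice is recorded in the run metadata.

The preprocessing order is fixed and enforced: variance filtering happens
on the raw scale (after z-scoring every feature has variance 1 and the
filter would be meaningless), then samples are aligned across blocks, then
columns are z-scored on the final sample set. The variance filter defaults
to dropping the lowest quartile for methylation blocks only — the largest
block by an order of magnitude, where near-constant probes are common —
and to no filtering for CNA and miRNA.

## The selection procedure

Per gene, the package runs a two-stage Screen-and-Clean:

1. **Screen.** Half the samples (a 50/50 split drawn from the gene's seed)
   are used to fit the lasso, with $\lambda$ chosen by 10-fold
   cross-validation *inside the screen half* over a geometric grid of 100
   penalties from $\lambda_{\max}$ down to $10^{-3}\lambda_{\max}$,
   minimizing held-out squared error (ties resolve to the larger, sparser
   penalty). The nonzero coefficients form the candidate set.
2. **Clean.** The other half of the samples — never touched by screening —
   yields OLS estimates and two-sided t-tests for the candidate features.
   Features with $p \le 0.05$ are selected; their clean-stage coefficient
   magnitudes are the association strengths. No multiple-testing
   correction is applied across features or genes: the flat 0.05
   threshold is the procedure's operating point, and because the halves
   are disjoint the per-tested-feature false-selection rate is controlled
   at its nominal level (the test suite verifies both the rate and the
   uniformity of null p-values).

Two details matter for validity and are deliberate:

* The clean-stage OLS **includes an intercept** even though the lasso
  stage does not. Traits are centred globally; a random half of the
  samples has a nonzero mean, and omitting the intercept would leak that
  mean into the slopes and bias the t-tests.
* The split, the CV folds, and everything else randomized are derived
  from one seed per gene, itself derived from the run seed and the gene's
  index. Fits are therefore reproducible bit-for-bit and independent of
  execution order or of which subset of genes is requested.

Degenerate situations are handled explicitly rather than silently: if the
candidate set is too large for the clean regression it is truncated to the
largest-magnitude screen coefficients that keep OLS overdetermined (and
flagged); exactly collinear candidates are dropped and recorded; an empty
candidate set is a valid result, not an error.

## Numerical choices

The lasso solver is cyclic coordinate descent (compiled code) on the
objective exactly as written above — RSS plus $\lambda\lVert\beta\rVert_1$
with no $1/2N$ factor. Final fits converge to a strict tolerance
($10^{-11}$ relative coefficient change by default; the KKT residuals of
returned solutions are checked in the tests against an independent
accelerated-proximal-gradient oracle and against closed forms on
orthonormal designs). The cross-validation paths use a moderate tolerance
($10^{-5}$), a 50-sweep cap per grid point and a saturation early-stop
(once the training RSS falls below $10^{-3}\sum y_i^2$ the remaining,
even-smaller penalties reuse the current solution): held-out error is
insensitive to the last digits of the training coefficients, and the
saturated tail — reachable whenever candidates outnumber training samples
— never minimises held-out error but dominates runtime if polished. The
penalty chosen is identical with and without these accelerations on the
instances we examined; only the final fit's coefficients are ever
reported.

## Prediction accuracy

The headline accuracy of a gene's model is the Pearson correlation between
observed and predicted expression **under 5-fold cross-validation**:
within each fold, selection (Screen-and-Clean) and estimation are re-run
from scratch on the training folds, associations weaker than
$\rho = 0.1$ are discarded, the model is refit by OLS on the survivors,
and the held-out samples are predicted; pooled predictions are then
correlated with the observed trait. The in-sample correlation is also
computed and stored, but it is optimistically biased — the features were
chosen to fit these very samples — so it is never the headline number.
Genes whose folds never produce a model score 0 with a `no_model` flag;
constant predictions are flagged `undefined` and count as 0 in aggregates.

## From coefficients to analytics

All analytics are pure functions of the fitted coefficient table and a
configuration, with deterministic tie-breaks, so reruns reproduce every
table byte-for-byte:

* **Edges**: one association per (gene, feature) with nonzero cleaned
  coefficient and strength $\ge \rho$; $\rho = 0.1$ is the analysis
  default, $\rho = 0.3$ the network default. Edges sort by strength, then
  gene, then feature.
* **Venn classes**: a gene with at least one edge belongs to exactly one
  of 7 classes (3 single types, 3 pairs, all three); counts partition the
  genes with any edge. Genes in multi-type classes are the "synergistic"
  genes.
* **Deciles**: genes ranked by mean expression $\mu$, standard deviation
  $\sigma$, or $\mu/\sigma$, split into 10 contiguous equal-sized bins
  (remainder to the lowest bins, ties broken by gene id).
* **Top-K contribution**: among the K strongest edges, the proportion of
  distinct (gene, type) pairs per type — a gene with three methylation
  edges counts once for methylation, because the quantity of interest is
  the proportion of *genes* associated with each type. The alternative
  (counting edges) is recorded in output metadata as not used.
* **Hubs**: features ranked by distinct-gene degree, ties lexicographic;
  per-hub gene lists are exported as plain text for external enrichment
  tools (enrichment itself is out of scope).
* **Cis flags**: a methylation edge is cis when its feature maps to its
  own gene; the default map is symbol identity, and a user-supplied map
  can replace it. No genomic-distance rule is attempted.

## The association network

The network is strictly bipartite (features on one side, genes on the
other), built from edges at $\rho = 0.3$ with isolated nodes removed.
Two diagnostics need care in a bipartite graph:

* The ordinary (triangle) clustering coefficient is identically zero, so
  the package reports the **square-based clustering coefficient** — the
  fraction of potential 4-cycles through a node that are realised — and
  says so in its output metadata.
* **Modularity** Q uses the standard Newman definition on the unweighted
  graph, with the partition found by deterministic greedy agglomeration.
  Closed-form anchors (two disconnected 4-cycles give Q = 1/2; complete
  bipartite $K_{2,2}$ has square clustering 1 at every node) are asserted
  in the tests.

Exports are Cytoscape-compatible SIF, GraphML and TSV with byte-stable
ordering; GraphML and TSV round-trip all attributes, SIF (by format
design) carries only topology and the feature type as the interaction
label.

## The synthetic-data generator

The generator emulates the shapes and value families of a tumor
multi-omics study at desk scale, with a known sparse ground truth:

* **Marginals.** CNA features are categorical calls in $\{-2,\dots,2\}$
  obtained by thresholding a latent Gaussian (default mass
  0.05/0.15/0.6/0.15/0.05); methylation features are logit-normal
  beta-values in (0,1); miRNA features are Gaussian signals. Defaults are
  10 CNA / 300 methylation / 80 miRNA features, preserving the
  CNA ≪ miRNA ≪ methylation proportions of cytoband-level CNA against
  array methylation, with N = 200 samples and 100 genes.
* **Traits.** Each driven gene's trait is a sparse linear combination
  (s = 3 true features by default, magnitudes uniform on [0.3, 1] with
  random signs) of the *z-scored* features plus $N(0, \sigma^2)$ noise
  with $\sigma = 1$. By default 10% of genes are null, 40% are driven by
  exactly two feature types, and the rest by a single type. No gene is
  genuinely driven by all three types: that makes the all-three Venn
  class of any analysis a pure read-out of spurious synergy, which is
  exactly what the integrative-versus-single benchmark is meant to
  isolate.
* **Cross-type correlation.** Each causal feature of a single-type-driven
  gene is paired with a partner feature in another type; the pair shares
  a latent Gaussian factor at correlation `cross_type_rho` (default 0.7)
  *before* the marginal transforms, preserving each type's marginal
  family. This is the minimal mechanism that makes single-type analyses
  attribute a trait to feature types that do not drive it.
* **Archetypes.** CNA-driven genes receive high mean offsets and
  methylation-driven genes amplified effects (hence higher trait
  variance), linking the $\mu$/$\sigma$ decile structure to the driving
  type the way highly expressed genes track gene dosage and variably
  expressed genes track epigenetic regulation.

What the generator does **not** emulate: genomic coordinates and linkage
structure, copy-number segment lengths, pervasive low-level correlation
among all features of a type, heavy-tailed expression noise, or batch
structure. Passing benchmarks on this generator therefore demonstrates
that the procedure behaves as designed under its own assumptions — sparse
additive signal, Gaussian noise, localized cross-type correlation — not
that it is robust to everything real tumor data can do.

## Benchmark instruments and problem sizes

`spurious_benchmark()` fits every gene in integrative mode and in the
three single-type modes and tabulates, per replicate dataset: the
all-three-types Venn class size under each analysis (for the single-type
analysis, a gene counts for type m when the separate type-m fit selects
anything), the number of *false-type* edges (edges whose feature type is
not among the gene's true driving types), and optionally per-mode
cross-validated accuracies on the two-type-driven genes and the network
modularities.

The packaged test suite and the acceptance script run these instruments at
reduced sizes chosen to finish on a single CPU while keeping the pinned
study conditions (sample sizes, noise level, correlation strength,
replicate counts) intact: recovery uses N = 300, s = 3, σ = 1 over 50
replicates with 6 driven genes and 6/60/24 features per type; the
spurious benchmark uses cross_type_rho = 0.7 over 30 replicates with
N = 200 and 5/40/15 features (50 genes per replicate in the test suite,
70 in the acceptance script); the prediction comparison uses 50
replicate datasets with N = 120 and 4/20/8 features, scoring the
two-type-driven genes; the null calibration uses 500 replicates at
N = 200, J = 50.

## Known limitations

* Cross-validation at the minimum of the held-out error curve is known to
  over-select; with the flat per-feature 0.05 clean threshold this puts a
  floor of about $0.05 \times$ (screened null candidates) false features
  per gene under the procedure's own operating point. With s = 3 true
  features per gene the recovery F1 therefore degrades as the candidate
  pool grows: at the packaged scale (90 features) the median sits near
  0.9, but at several hundred features it drops toward 0.85 from false
  positives alone. Tightening would require either a multiple-testing
  correction or the one-standard-error CV rule, both of which would
  change the procedure being studied, so neither is applied.
* Clean-stage coefficient RMSE on the true support scales like
  $\sigma/\sqrt{n_{\text{clean}}}$ inflated by collinearity with partner
  features; at N = 300 and cross-type correlation 0.7 it sits near 0.1.
* The cis rule is symbol identity, not genomic distance.
* Everything is additive; interaction terms between feature types are out
  of scope by design.
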