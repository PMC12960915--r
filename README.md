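# omicsweave

Integrative analysis of multi-omics experiments in R: import, preprocessing,
latent-variable integration, method comparison, and consensus feature
ranking, wrapped in a make-like reproducible pipeline engine.

## The problem

Multi-omics studies measure several molecular layers (transcripts, proteins,
metabolites, genotypes, ...) on overlapping sets of biological samples. The
usual way to analyse them jointly is latent-variable integration: construct a
small number of latent dimensions, each a weighted combination of features
from one or more omics datasets, with one score per sample per dimension.
Many methods do this — sparse PLS, multi-block PCA, factor analysis — and
there is no gold standard: each behaves differently depending on data type,
sample size and signal structure. Practitioners therefore want to run several
methods on the same data and ask (i) do they find the same sample-level
trends, (ii) do they prioritise the same features, and (iii) what does a
robust, method-agnostic feature ranking look like?

`omicsweave` is built around that workflow, for analysts who work in R and
want every step — from CSV import to the consensus ranking — scripted,
seeded and cache-invalidated.

## What is in the box

* **Data management** — `omics_dataset` (matrix + features/samples metadata),
  `multiomics_set` (shared sample namespace, metadata-conflict validation),
  CSV and GFF3/GTF import, UpSet-style exclusive sample-overlap counts.
* **Preprocessing** — missingness and mean–SD diagnostics, NIPALS PCA that
  tolerates missing cells, iterative PCA imputation, log2/half-minimum,
  log2(x+1), z-score and custom transforms with a per-dataset transformation
  log, MAD/COV unsupervised prefiltering and sPLS-DA supervised prefiltering.
* **Integration** — native two-block sparse PLS (`spls`), sparse PLS
  discriminant analysis (`splsda`), consensus multi-block PCA
  (`consensus_mbpca`), plus an adapter registry for external methods.
* **Standard output** — every result becomes two tables (feature weights,
  sample scores). The importance of feature *i* on dimension *j* is

  `m_ij = |w_ij| / max_i' |w_i'j|`

  with the maximum over features of the same omics dataset, so importances
  live in [0, 1] and are comparable across methods while raw weights are not.
* **Evaluation** — silhouette scores of sample groupings in latent space,
  feature-weight vs metadata-label comparisons, selection contingency
  tables, and feature-set enrichment (Welch *t* of member vs non-member
  importances, Benjamini–Hochberg adjusted).
* **Comparison & consensus** — Pearson/Spearman correlation of sample scores
  and feature weights between any two results, clustered correlation
  heatmaps, greedy dimension matching, and consensus importance
  `cm_i = f(m_i,d1, ..., m_i,dJ)` with `f` one of average, geometric mean,
  harmonic mean, L2 norm (`sqrt(sum m^2)`) or product. Geometric/harmonic
  favour features supported by *all* methods; L2 also surfaces
  single-method signals.
* **Pipeline engine** — named steps form a DAG; each step re-executes only
  when its operation version, parameters, input files or an ancestor's
  output change; each step gets a deterministic seed derived from the global
  seed and the step name; outputs are cached and retrievable; run metadata
  (hash, seed, status, runtime) is recorded as JSON lines.
* **Synthetic data** — `generate_multiomics()` simulates blocks sharing
  latent factors with sparse loadings, a group effect on factor 1, MCAR
  missingness and partial sample overlap, returning the ground truth for
  benchmarking.

## Worked example

Simulate three omics blocks over 100 samples sharing one group-linked latent
factor, run two integration methods, compare them, and rank features:

```r
library(omicsweave)

sim <- generate_multiomics(sim_config(seed = 42))
sim$data
#> <multiomics_set> 3 dataset(s), 100 samples in registry
#>   - rna: 200 features x 100 samples
#>   - protein: 150 features x 100 samples
#>   - metabolite: 100 features x 100 samples

fit_spls <- spls(get_dataset(sim$data, "rna"), get_dataset(sim$data, "protein"),
                 ncomp = 2, keepX = 40, keepY = 30, names = c("rna", "protein"))
fit_mb   <- consensus_mbpca(sim$data, ncomp = 2)

dr_spls <- to_standard_output(fit_spls, method_label = "spls")
dr_mb   <- to_standard_output(fit_mb,   method_label = "mbpca")

match_dimensions(correlate_results(dr_spls, dr_mb), threshold = 0.8)
#> # A tibble: 1 × 4
#>   dim_a       dim_b       r_scores r_weights
#> 1 Component 1 Component 1    0.999     0.958
```

The two methods' first dimensions are near-identical in both sample trends
(r = 0.999) and feature rankings (r = 0.958) — they found the same shared
factor. That dimension separates the two simulated sample groups:

```r
groups <- setNames(get_dataset(sim$data, "rna")$samples_meta$group,
                   get_dataset(sim$data, "rna")$samples_meta$sample_id)
silhouette_scores(dr_mb, groups, dimensions = "Component 1")$groups
#> # A tibble: 2 × 3
#>   group      n mean_silhouette
#> 1 groupA    50           0.504
#> 2 groupB    50           0.476
```

A geometric-mean consensus over the two methods ranks features that both
methods agree on:

```r
cons <- consensus_importance(list(spls = compute_importance(dr_spls),
                                  mbpca = compute_importance(dr_mb)),
                             "Component 1", aggregation = "geometric")
head(cons, 3)
#> # A tibble: 3 × 5
#>   feature_id dataset m_spls m_mbpca consensus
#> 1 P_072      protein  1       1         1
#> 2 R_189      rna      1       1         1
#> 3 R_106      rna      0.999   0.999     0.999
```

All top-ranked features are truly active on the shared factor
(`sim$truth$active`); on this instance the consensus ranking separates
active from inactive features with AUC 1.0.

The same analysis can be written as a cached pipeline (see
`?build_pipeline`, `?run_pipeline`, `?target_factory`): steps re-run only
when something they depend on changes, and every stochastic step's seed is
derived from the global seed and the step name, so two machines produce
bit-identical results.

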